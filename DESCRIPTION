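Package: bc4d4
Title: ECoG Finger-Flexion Decoding with Isolation-Forest Cleaning and
    the BC4D4 Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for regression decoding of continuous finger
    flexion from multichannel electrocorticography (ECoG) in the layout
    of the BCI Competition 4 Dataset 4 (per-subject signal matrices
    paired with five dataglove traces). Provides descriptive profiling
    of recordings (five-number summaries, IQR outlier flagging,
    descriptive-statistics tables), a from-scratch isolation-forest row
    cleaner, the BC4D4 one-dimensional convolutional plus dense
    regression network with configurable bounded activation functions
    (tanh, softsign and six others), per-finger Pearson-correlation
    evaluation, readers and writers for MAT/HDF5/CSV recordings, a
    synthetic ECoG/dataglove simulator with known ground truth, and a
    reproducible end-to-end pipeline runner with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    rhdf5,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
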