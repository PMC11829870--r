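# bc4d4: ECoG finger-flexion decoding with isolation-forest cleaning

`bc4d4` is an R toolkit for regression decoding of continuous finger
flexion from multichannel electrocorticography (ECoG), built around the
data layout of the BCI Competition 4 Dataset 4: per subject, a z-scored
feature matrix (samples × channels; 62/48/64 channels for the three
canonical subjects) paired with five dataglove flexion traces recorded
while the subject flexes individual fingers on cue. It is aimed at BCI
researchers who want a tested, scriptable implementation of this
pipeline — statistical profiling, outlier removal, a CNN+dense decoder,
and per-finger correlation evaluation — that can be exercised end-to-end
on a bundled synthetic simulator with known ground truth, without
downloading the competition data.

## The method

**Profiling.** Raw dataglove traces are abrupt: quartiles hug the mean
while maxima sit 5–8 standard deviations out. The package computes
five-number summaries (min, Q1, median, Q3, max; quartiles by linear
interpolation between order statistics), IQR whisker flags
(x < Q1 − k·IQR or x > Q3 + k·IQR, k = 1.5), and descriptive tables
(count, mean, std, min, 25%, 50%, 75%, max).

**Isolation-forest cleaning** (from scratch). Each of `n_trees = 100`
trees grows on a ψ = 256 row subsample by splitting on a random feature
at a random threshold inside that feature's range, to height
⌈log₂ ψ⌉. With h(x) the path length of x (plus the adjustment
c(m) = 2H(m−1) − 2(m−1)/m at a leaf holding m points), the anomaly score
is

    s(x) = 2^( −E[h(x)] / c(ψ) )

and cleaning keeps the ⌈(1 − contamination)·n⌉ lowest-scoring rows. The
default contamination of 0.70 reproduces the published 60,000 → 18,000
pre/post row counts for this dataset (and is documented as unusually
aggressive — set it near your outlier rate on other data).

**The BC4D4 network.** Input window of length `ip` (the channel vector,
in the default channels-as-sequence mode) → Conv1D(64) → Conv1D(128) →
Conv1D(256) (kernel 3, no padding, ReLU) → flatten → Dense 1024 →
Dropout 0.1 → Dense 512 → 256 → 128 → 64 → 1, with tanh or softsign
(x/(1+|x|)) on every dense layer including the output head — bounded,
signed activations matched to cleaned flexion targets that lie mostly in
(−1, 1). Forward, backward and Adam are implemented in-package with
BLAS-batched matrix algebra and are bit-reproducible from a seed.
`count_parameters()` reproduces the architecture's per-layer ledger
(3·in·out + out per conv, in·out + out per dense).

**Evaluation.** One network per finger; Pearson correlation r between
prediction and truth on a held-out chronological tail, reported per
finger with the five-finger average.

## Worked example

```r
library(bc4d4)

# a 40 s, 16-channel synthetic session: 5 fingers, raised-cosine flexion
# events, linear channel coupling at SNR 5, 2% spike outliers
sim <- simulate_recording(sim_config(
  n_channels = 16, duration_s = 40, sample_rate_hz = 50,
  events_per_finger = 12, coupling_snr = 5, outlier_fraction = 0.02,
  seed = 7))
sim$recording
#> <recording> subject 'synthetic': 2000 samples, 16 channels, 5 fingers
#>   sample rate: 50 Hz; fingers: thumb, index, middle, ring, little

# the injected spikes dominate the tails of the raw traces
head(describe(sim$recording, "targets")[, c("column", "mean", "std", "max")], 2)
#>   column         mean std      max
#> 1  thumb 5.077319e-18   1 6.339246
#> 2  index 4.486456e-18   1 6.933633

# drop the anomalous rows (per-finger forests, contamination = 2x the
# injection rate), then check against the simulator's ground truth
cl <- clean_recording(sim$recording, clean_config(0.04, "per_finger"),
                      seed = 7)
spikes <- rowSums(sim$truth$outlier_mask) > 0
mean(!cl$kept[spikes])   # fraction of spike rows removed
#> [1] 0.9946809

# train one decoder per finger on the chronological first 80%,
# evaluate on the last 20%
split <- split_recording(cl$recording, 0.2)
models <- fit_decoders(split$train, "softsign", window_config(),
                       train_config(epochs = 12, seed = 11))
evaluate_decoders(models, split$test)
#> <evaluation_report> subject synthetic, softsign head
#>  thumb  index middle   ring little    avg
#> 0.9592 0.9586 0.9559 0.9720 0.9653 0.9622
```

The held-out correlations sit near the simulator's SNR-limited ceiling;
on real cortical data the coupling is not linear and correlations are
lower. A command-line wrapper with the same stages
(`simulate`, `convert`, `profile`, `clean`, `train`, `evaluate`,
`pipeline`) is installed at `inst/cli/bc4d4`, and `run_pipeline()`
executes all five stages from one plain-text config with a checksummed
run manifest.

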