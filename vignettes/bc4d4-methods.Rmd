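---
title: "Decoding finger flexion from ECoG: methods and design notes"
author: "bc4d4 package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger flexion from ECoG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bc4d4)
```

## The decoding problem

Electrocorticography (ECoG) records electrical potentials from electrode
grids placed directly on the cortical surface. In the finger-flexion
paradigm this package targets, a subject flexes individual fingers on cue
(a finger name shown for 2–3 s, followed by 2–3 s of rest) while a
dataglove records the continuous flexion of all five fingers; a session
lasts about ten minutes and contains roughly 30 flexion events per finger.
The decoding task is regression: predict each finger's continuous flexion
trace from the multichannel ECoG features, scored by the Pearson
correlation between prediction and truth — the standard metric for this
paradigm. Subjects differ only in channel count (62, 48 and 64 in the
canonical three-subject layout); the distributed feature matrices are
z-scored per column.

The pipeline has four stages, each usable on its own:

1. **Profiling** — five-number summaries, IQR whisker flagging and
   descriptive tables, which show the raw dataglove traces to be abrupt:
   quartiles sit near the mean while the maxima lie 5–8 standard
   deviations out, i.e. the traces are contaminated by heavy-tailed
   artifacts.
2. **Isolation-forest cleaning** — rows whose anomaly score is high are
   dropped; the retained core is near-Gaussian and signed, mostly inside
   (−1, 1).
3. **The BC4D4 network** — three 1-D convolutions (64/128/256 filters,
   kernel 3, no padding) feeding a dense chain 1024→512→256→128→64→1 with
   dropout 0.1 after the first dense layer.
4. **Evaluation** — per-finger Pearson correlations on a held-out
   chronological tail, with tanh and softsign dense heads compared on
   identical data and seeds.

## The synthetic recording generator

Real competition recordings cannot ship with a package, so every stage is
exercised against `simulate_recording()`, which generates data with the
statistical structure the pipeline assumes and a known ground truth:

* **Flexion traces.** Each finger receives `events_per_finger`
  raised-cosine bumps (default 30 over a 600 s session). Onsets follow a
  cue/rest cadence drawn from 2–3 s intervals, with the remaining idle
  time spread randomly between events. A raised cosine is smooth, bounded
  and unimodal — the only properties downstream stages rely on; any
  similar kernel would do.
* **Channels.** `signals = clean_targets %*% t(mixing) + noise`, with a
  Gaussian `mixing` matrix and band-limited Gaussian noise (white noise
  smoothed by a 5-tap moving average) scaled per channel so the
  signal-to-noise ratio equals `coupling_snr` (default 5). The linear
  coupling gives decoding a verifiable ceiling: with no outliers and very
  large SNR an ordinary least-squares readout recovers each trace with
  r ≥ 0.99, so a decoder that fails here is broken, not unlucky.
* **Outliers.** A fraction `outlier_fraction` (default 0.02) of samples
  per finger is spiked by ±`outlier_scale` (default 6) standard
  deviations with random sign, reproducing the abrupt tails of the raw
  descriptive tables (a near-zero mean with a maximum near 6).
* **Standardization.** Both matrices are z-scored per column after
  injection, matching the form in which the real data are distributed.
* **Sampling rate.** The canonical recordings have 60,000 rows per
  10-minute session; the generator's default of 100 Hz × 600 s reproduces
  that count. Whether those rows are truly time samples at 100 Hz is not
  derivable from the published description; the simulator treats them as
  time samples, and the rate is configurable.

The generator draws everything from a single seeded stream, so a
`SimConfig` is a complete provenance record. It is a statistical stand-in,
not a biophysical model: it has no 1/f spectrum, no line noise, no
spatial electrode correlation beyond the shared mixing, and no
inter-subject variability beyond the channel count. Tests passing on it
show the pipeline machinery is correct under its assumptions
(linear coupling, additive noise, spike-type outliers); they do not show
that any particular correlation is attainable on real cortical data.

## Profiling conventions

Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7). Conventions differ by O(1/n) and the
published tables do not say which was used; one is fixed here so results
are deterministic. Standard deviations are population (n) throughout,
consistent with `zscore_columns()`; at n = 60,000 the n vs n−1 difference
is ~1e−5, far below the 2-decimal precision of the descriptive tables,
and the population form lets a single-sample column report std 0 rather
than NA. The box-plot outlier rule flags points outside
[Q1 − k·IQR, Q3 + k·IQR] with k = 1.5 by default (the prose description
"outside the minimum and maximum" is read as the standard whisker rule,
which is what the accompanying box plots show).

## Isolation-forest cleaning

The scorer is written from scratch (it is part of the method, not a
borrowed step): each of `n_trees` (default 100) trees is grown on a
`psi`-row subsample (default 256, drawn without replacement), splitting on
a uniformly random feature at a uniformly random threshold strictly
between that feature's minimum and maximum in the node, to a height limit
of `ceiling(log2(psi))`. A query's path length is the number of edges to
its leaf plus the adjustment `c(m)` for a leaf that still holds `m > 1`
training points, where

  c(m) = 2·H(m−1) − 2·(m−1)/m,  c(1) = 0,

the average unsuccessful-search depth of a binary search tree. The score
is `s(x) = 2^(−E[h(x)]/c(psi))`: 0.5 for a point as deep as an average
point, approaching 1 for points isolated in very few splits. Harmonic
numbers are exact (H(1) = 1, so c(2) = 1); implementations that use the
ln + Euler–gamma approximation shift c(2) to ≈ 0.154, which changes
scores by a small monotone amount and ranks not at all — rank agreement
with an independent reference implementation is what the test suite
checks (Spearman ≥ 0.95 plus top-rank agreement on a planted outlier).

Cleaning keeps the `ceiling((1 − contamination)·n)` lowest-scoring rows,
ties at the boundary broken by row index, so the kept count is exact and
deterministic. Design choices worth knowing:

* **contamination defaults to 0.70.** The published pre/post cleaning
  tables go from 60,000 to 18,000 rows per finger, implying a 0.30 keep
  fraction. Removing 70 % of the data is far outside normal
  isolation-forest practice (where contamination approximates the actual
  outlier rate); the default reproduces the published counts, and the
  parameter is exposed precisely because users on other data should set
  it near their expected outlier fraction instead.
* **scope = "joint"** (one forest on signals ‖ targets) keeps
  signal/target row alignment trivially correct and the kept count
  exact. `"per_finger"` grows one forest per dataglove trace and
  intersects the per-finger keep masks, which reproduces per-finger
  counting but can keep fewer than the nominal fraction. The published
  description does not say which matrices the forest saw; both are
  provided.
* **No re-standardization after cleaning** (`re_zscore = FALSE`): the
  published post-cleaning standard deviations are well below 1, which is
  only possible if the cleaned data were not re-z-scored. A flag restores
  re-scoring for users who want it.

## Activation functions

Eight elementwise activations are implemented exactly: sigmoid, ReLU,
LeakyReLU, tanh (in its 2/(1+e^(−2x)) − 1 form, identical to
2·sigmoid(2x) − 1), softsign x/(1+|x|), ReLU6, CELU and HardShrink. Two
notes:

* LeakyReLU is sometimes written as the single line f(x) = 0.01x, which
  would make it a scalar multiple of the identity; the standard two-slope
  piecewise form (x for x > 0, 0.01x otherwise) is implemented, and the
  function documentation records both facts.
* CELU's α (default 1) and HardShrink's λ (default 0.5) are standard
  defaults; no published value exists for this pipeline.

The signed bounded pair — tanh and softsign — matters because cleaned
flexion targets are dual-polarity and mostly inside (−1, 1). Softsign
saturates polynomially rather than exponentially, so its gradient decays
more slowly away from the origin; the package treats the choice as a
config value and compares the two heads on identical data and seeds.

## The BC4D4 network

`build_bc4d4(ip, dense_activation)` returns the fixed 11-layer
specification; `ip` is the input window length (the channel count in
channels-as-sequence mode, so 62/48/64 for the canonical subjects). Valid
kernel-3 convolutions shrink the length by 2 each, so `ip >= 7` and the
flatten width is `(ip − 6)·256`. Parameter accounting is
`3·in·out + out` per convolution and `in·out + out` per dense layer. At
`ip = 7` this reproduces the widely printed per-layer ledger for this
architecture at every arithmetically consistent entry (256; 24,704;
98,560; 524,800; 131,328; 32,896; 8,256; 65). The ledger's first dense
entry is printed as 256·1024 + 1024 = 262,144, but that arithmetic is
internally inconsistent (the sum is 263,168, and 262,144 is exactly
2^18); `count_parameters()` reports the consistent value and the help
page documents the discrepancy. Pooling is deliberately absent: on a
small corpus, the information discarded by pooling is not recoverable by
the dense block.

Choices the published description leaves open, fixed here:

* **Weight initialization**: Glorot-uniform from a seeded stream —
  appropriate for saturating tanh/softsign stacks. Configurable via the
  training seed.
* **Output head**: the dense activation is applied to the final
  single-unit layer too (the composed-function form of the architecture
  shows the head inside the activation). Cleaned targets sit mostly
  inside (−1, 1), and Pearson evaluation is invariant to the mild
  amplitude compression a bounded head causes.
* **Regularization**: "dropout & regularization" is interpreted as
  dropout 0.1 (printed) plus optional L2 weight decay, default
  coefficient 0 because no value is published anywhere.
* **The conv axis**: the published input shape suggests the per-sample
  feature vector, while the window-length variable suggests a temporal
  window. The model is parameterized by a single length `ip`; the
  windowing config binds it either to channels (`channels_as_sequence`,
  default) or to a temporal window of one channel (`time_window`).

The forward/backward pass is implemented with BLAS-batched matrix
algebra (an im2col view for the convolutions); gradients are verified
against central finite differences, and the evaluation-mode forward is a
pure function. Training uses minibatch Adam (default) or SGD on
mean-squared error; dropout is active only in training mode. Everything —
initialization, shuffling, dropout masks — derives from one seed, so a
run is bit-reproducible.

## Training and evaluation protocol

The published description states no optimizer, loss, epoch count,
batch size or train/test split; the package defaults to Adam, MSE,
50 epochs, batch 256 and a chronological 20 % tail held out for
evaluation. A chronological split is stricter than a shuffled one for
time series (no leakage of temporally adjacent samples across the
boundary) and `evaluate_decoders()` refuses to score a model on rows it
was trained on unless explicitly overridden. One network is trained per
finger (the architecture ends in a single output unit), and a report
carries the full window and training configuration for provenance.
Correlations are computed on raw held-out predictions with no
post-smoothing.

## Problem sizes used by the test and acceptance suites

The bundled verification experiments run at desk scale, chosen as the
smallest sizes at which each property is meaningfully testable:

* Cleaning-count and profiling checks use the full default simulation
  (60,000 samples × 62 channels), where the forest fit and scoring are
  fast.
* The decoding-recovery experiment uses a 16-channel, 2,000-sample
  recording (40 s at 50 Hz, 12 events per finger, SNR 5, 2 % outliers
  cleaned per finger at twice the injection rate) and 12 training epochs
  per finger model. Ten networks (five fingers × two activation heads)
  of ~2.9 M parameters each are trained in a few minutes of CPU time at
  this size, and the linear-coupling ceiling means the achievable
  correlation is limited by SNR, not by sample count.
* Oracle-equivalence checks for the forest use 500 × 5 Gaussian data
  with a planted outlier and 200 trees.

Scaling the decoding experiment up (62 channels, 60,000 samples,
50 epochs) changes runtime, not the code path: every setting above is an
ordinary config value.

## Known limitations

* The simulator's linear channel coupling makes the decoding task easier
  than real ECoG, where the flexion signal rides on broadband cortical
  dynamics; held-out correlations on synthetic data are a ceiling check,
  not a forecast of real-data performance.
* A 70 % contamination default is specific to reproducing the published
  cleaned row counts and is aggressive for general use.
* The MAT reader covers level-5 files with plain or zlib-compressed 2-D
  numeric variables — the subset the competition files and common
  scientific writers produce. Cell arrays, structs, sparse and complex
  variables are skipped with a warning; v7.3 (HDF5-based) files belong
  to the HDF5 path.
* Training runs on CPU via BLAS; it is adequate for the desk-scale
  experiments above but not tuned for full-scale hyperparameter sweeps.
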