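#' Multichannel ECoG recording paired with dataglove targets
#'
#' The shared container of the toolkit: a samples-by-channels signal matrix
#' and a samples-by-fingers flexion target matrix, with sampling metadata.
#' Samples are always on the first axis. Both matrices are conventionally
#' z-scored per column (mean 0, standard deviation 1), the form in which the
#' competition data are distributed.
#'
#' @param signals numeric matrix, samples x channels.
#' @param targets numeric matrix, samples x fingers (same sample count).
#' @param sample_rate_hz samples per second, or `NA` when unknown.
#' @param subject_id character label for the subject.
#' @param finger_names ordered finger labels; length must match
#'   `ncol(targets)`. Default is the conventional thumb-to-little order.
#'
#' @return An object of class `"recording"`: a list with the fields above.
#' @examples
#' rec <- recording(matrix(rnorm(40), 10, 4), matrix(rnorm(50), 10, 5))
#' rec
#' @export
recording <- function(signals, targets, sample_rate_hz = NA_real_,
                      subject_id = "synthetic",
                      finger_names = c("thumb", "index", "middle",
                                       "ring", "little")) {
  signals <- as.matrix(signals)
  targets <- as.matrix(targets)
  storage.mode(signals) <- "double"
  storage.mode(targets) <- "double"
  if (nrow(signals) != nrow(targets))
    stop_field("targets", sprintf(
      "sample counts differ: signals has %d rows, targets has %d",
      nrow(signals), nrow(targets)))
  if (ncol(targets) != length(finger_names))
    stop_field("finger_names", sprintf(
      "%d names for %d target columns", length(finger_names), ncol(targets)))
  if (anyNA(signals) || any(!is.finite(signals)))
    stop_field("signals", "contains NaN/Inf; drop or repair rows on load")
  if (anyNA(targets) || any(!is.finite(targets)))
    stop_field("targets", "contains NaN/Inf; drop or repair rows on load")
  colnames(targets) <- finger_names
  structure(
    list(signals = signals, targets = targets,
         sample_rate_hz = as.numeric(sample_rate_hz),
         subject_id = as.character(subject_id),
         finger_names = finger_names),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject '%s': %d samples, %d channels, %d fingers\n",
              x$subject_id, nrow(x$signals), ncol(x$signals),
              ncol(x$targets)))
  cat(sprintf("  sample rate: %s Hz; fingers: %s\n",
              ifelse(is.na(x$sample_rate_hz), "unknown",
                     format(x$sample_rate_hz)),
              paste(x$finger_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.recording <- function(x) c(nrow(x$signals), ncol(x$signals), ncol(x$targets))

n_samples <- function(rec) nrow(rec$signals)

#' Subset a recording by sample rows
#'
#' Keeps signals and targets aligned and records which original rows the
#' subset came from (attribute `"row_range"`), so that downstream evaluation
#' can refuse to score a model on its own training rows.
#'
#' @param rec a [recording()].
#' @param rows integer or logical index of samples to keep.
#' @return A new `recording` with the selected rows.
#' @export
subset_recording <- function(rec, rows) {
  stopifnot(inherits(rec, "recording"))
  idx <- seq_len(n_samples(rec))
  prev <- attr(rec, "row_range", exact = TRUE)
  if (is.null(prev)) prev <- idx
  keep <- prev[idx[rows]]
  out <- recording(rec$signals[rows, , drop = FALSE],
                   rec$targets[rows, , drop = FALSE],
                   rec$sample_rate_hz, rec$subject_id, rec$finger_names)
  attr(out, "row_range") <- keep
  out
}

#' Split a recording chronologically into train and test segments
#'
#' The held-out segment is the chronological tail: time-series decoding is
#' evaluated on data strictly after everything the model saw, so no window
#' can straddle the boundary.
#'
#' @param rec a [recording()].
#' @param test_fraction fraction in (0, 1) of samples held out at the end.
#' @return A list with `recording` elements `train` and `test`.
#' @export
split_recording <- function(rec, test_fraction = 0.2) {
  stopifnot(inherits(rec, "recording"))
  check_scalar_number(test_fraction, "test_fraction", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  n <- n_samples(rec)
  n_train <- floor(n * (1 - test_fraction))
  if (n_train < 1L || n_train >= n)
    stop_field("test_fraction", "leaves an empty train or test segment")
  list(train = subset_recording(rec, seq_len(n_train)),
       test  = subset_recording(rec, (n_train + 1L):n))
}

#' Z-score the columns of a matrix
#'
#' Standardizes every column to mean 0 and standard deviation 1 using the
#' population (n) denominator, the convention used for the distributed
#' competition data (per-finger standard deviations print as 1.00 at
#' n = 60,000, where the n vs n-1 distinction is ~1e-5).
#'
#' @param x numeric matrix or vector (treated as a one-column matrix).
#' @return Matrix of the same shape; each column has mean 0 +- 1e-9 and
#'   population standard deviation 1 +- 1e-9.
#' @examples
#' zscore_columns(cbind(c(1, 2, 3)))  # -1.2247, 0, 1.2247
#' @export
zscore_columns <- function(x) {
  if (is.vector(x)) x <- cbind(x)
  .zscore(x)
}
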