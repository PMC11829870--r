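#' Five-number summary of a trace
#'
#' Minimum, first quartile, median, third quartile and maximum -- the box
#' plot statistics used to screen every finger trace for outliers before
#' cleaning. Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); quartile conventions differ by O(1/n) and
#' this one is fixed so results are deterministic and testable.
#'
#' @param trace numeric vector, length >= 1, all finite.
#' @return A list of class `"five_number_summary"` with fields `minimum`,
#'   `q1`, `median`, `q3`, `maximum`.
#' @examples
#' five_number_summary(1:100)  # q1 = 25.75, median = 50.5, q3 = 75.25
#' @export
five_number_summary <- function(trace) {
  if (!is.numeric(trace) || length(trace) < 1L)
    stop_field("trace", "must be a non-empty numeric vector")
  if (any(!is.finite(trace)))
    stop_field("trace", "contains non-finite values")
  q <- unname(quantile(trace, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(list(minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 maximum = q[5]),
            class = "five_number_summary")
}

#' @export
print.five_number_summary <- function(x, ...) {
  cat(sprintf("min %.4g | Q1 %.4g | median %.4g | Q3 %.4g | max %.4g\n",
              x$minimum, x$q1, x$median, x$q3, x$maximum))
  invisible(x)
}

#' Flag outliers by the box-plot whisker rule
#'
#' Flags every point outside `[Q1 - k*IQR, Q3 + k*IQR]`, the whisker rule of
#' the box plots used to screen the raw traces ("a data point outside the
#' whisker range is an outlier"). For a Gaussian trace and k = 1.5 this
#' flags about 0.7% of points.
#'
#' @param trace numeric vector, length >= 4.
#' @param whisker_k positive whisker multiplier (default 1.5).
#' @return Logical vector marking flagged points.
#' @examples
#' iqr_outlier_mask(c(0, 0, 0, 0, 100))  # only the 100 is flagged
#' @export
iqr_outlier_mask <- function(trace, whisker_k = 1.5) {
  if (!is.numeric(trace) || length(trace) < 4L)
    stop_field("trace", "needs at least 4 points for quartiles")
  check_scalar_number(whisker_k, "whisker_k", 0, open_lower = TRUE)
  fns <- five_number_summary(trace)
  iqr <- fns$q3 - fns$q1
  trace < fns$q1 - whisker_k * iqr | trace > fns$q3 + whisker_k * iqr
}

#' Descriptive statistics table for a recording
#'
#' One row per column of the chosen side, in the column order
#' count, mean, std, min, 25%, 50%, 75%, max used by the descriptive tables
#' the raw and cleaned competition data are summarized with. The standard
#' deviation uses the population (n) denominator, matching
#' [zscore_columns()]; a single-sample column therefore reports std 0.
#'
#' @param rec a [recording()].
#' @param side `"targets"` (finger traces, default) or `"signals"`
#'   (channels).
#' @return A `data.frame` with columns `column`, `count`, `mean`, `std`,
#'   `min`, `p25`, `p50`, `p75`, `max`.
#' @export
describe <- function(rec, side = c("targets", "signals")) {
  stopifnot(inherits(rec, "recording"))
  side <- match.arg(side)
  m <- rec[[side]]
  labels <- if (side == "targets") rec$finger_names
            else sprintf("chan_%d", seq_len(ncol(m)))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    data.frame(column = labels[j], count = length(x), mean = mean(x),
               std = sqrt(mean((x - mean(x))^2)), min = min(x),
               p25 = q[1], p50 = q[2], p75 = q[3], max = max(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a descriptive table as CSV in the statistics-by-finger layout
#'
#' Rows are statistics (count, mean, std, min, 25%, 50%, 75%, max) and
#' columns are fingers/channels, mirroring the printed descriptive tables.
#'
#' @param desc output of [describe()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_describe_csv <- function(desc, path) {
  stats_names <- c("count", "mean", "std", "min", "p25", "p50", "p75", "max")
  wide <- data.frame(stat = stats_names,
                     lapply(seq_len(nrow(desc)), function(i)
                       unlist(desc[i, stats_names])),
                     check.names = FALSE)
  names(wide) <- c("stat", desc$column)
  data.table::fwrite(wide, path)
  invisible(path)
}
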