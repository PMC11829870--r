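#' @useDynLib bc4d4, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif sd var cor filter plogis rbinom
#' @importFrom utils head tail modifyList
NULL

# Run `code` under set.seed(seed) without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                integer = FALSE, open_lower = FALSE,
                                open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (integer && x != round(x))
    stop_field(field, "must be a whole number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must be in %s%s, %s%s",
                              if (open_lower) "(" else "[", format(lower),
                              format(upper), if (open_upper) ")" else "]"))
  invisible(x)
}

# Column-wise population z-score used throughout; kept internal so both
# zscore_columns() and the simulator share one implementation.
.zscore <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  bad <- which(sdev == 0)
  if (length(bad))
    stop(sprintf("column %d has zero variance and cannot be z-scored",
                 bad[1L]), call. = FALSE)
  sweep(sweep(x, 2L, mu), 2L, sdev, "/")
}
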