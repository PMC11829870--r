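ACTIVATION_NAMES <- c("sigmoid", "relu", "leaky_relu", "tanh", "softsign",
                      "relu6", "celu", "hardshrink")

#' Activation function specification
#'
#' The eight activation functions the decoder was screened against. The
#' signed, bounded pair tanh and softsign matter most here: cleaned flexion
#' targets are dual-polarity and mostly inside (-1, 1), so a dense head
#' with a bounded odd activation matches the target range.
#'
#' Definitions (elementwise):
#' * sigmoid: 1 / (1 + exp(-x))
#' * relu: max(0, x)
#' * leaky_relu: x for x > 0, `leak * x` otherwise. Note: some descriptions
#'   reduce this to the single line `0.01 x`, which would make it a scalar
#'   multiple of the identity; the standard two-slope piecewise form is what
#'   is implemented, with `leak = 0.01` by default.
#' * tanh: 2 / (1 + exp(-2x)) - 1
#' * softsign: x / (1 + |x|)
#' * relu6: min(max(0, x), 6)
#' * celu: x for x > 0, `alpha * (exp(x / alpha) - 1)` otherwise
#' * hardshrink: x for |x| > lambda, 0 otherwise
#'
#' @param name one of `r paste(ACTIVATION_NAMES, collapse = ", ")`.
#' @param alpha positive scale of the celu negative branch (celu only,
#'   default 1).
#' @param lambda positive dead-zone half-width (hardshrink only,
#'   default 0.5).
#' @param leak negative-side slope (leaky_relu only, default 0.01).
#' @return A list of class `"activation_spec"`.
#' @examples
#' apply_activation(activation("softsign"), c(-1, 0, 1))
#' @export
activation <- function(name, alpha = 1.0, lambda = 0.5, leak = 0.01) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% ACTIVATION_NAMES))
    stop_field("name", paste("must be one of",
                             paste(ACTIVATION_NAMES, collapse = ", ")))
  spec <- list(name = name)
  if (name == "celu") {
    check_scalar_number(alpha, "alpha", 0, open_lower = TRUE)
    spec$alpha <- alpha
  }
  if (name == "hardshrink") {
    check_scalar_number(lambda, "lambda", 0, open_lower = TRUE)
    spec$lambda <- lambda
  }
  if (name == "leaky_relu") {
    check_scalar_number(leak, "leak")
    spec$leak <- leak
  }
  structure(spec, class = "activation_spec")
}

as_activation <- function(x) {
  if (inherits(x, "activation_spec")) x else activation(x)
}

#' Apply an activation function elementwise
#'
#' @param spec an [activation()] spec (or a name, coerced).
#' @param x numeric scalar, vector, matrix or array; finite.
#' @return Same shape as `x`. Sigmoid and tanh are overflow-safe for
#'   arbitrarily large |x| (they saturate instead of producing NaN).
#' @export
apply_activation <- function(spec, x) {
  spec <- as_activation(spec)
  switch(spec$name,
    sigmoid = plogis(x),
    relu = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, spec$leak * x),
    tanh = tanh(x),
    softsign = x / (1 + abs(x)),
    relu6 = pmin(pmax(x, 0), 6),
    celu = ifelse(x > 0, x, spec$alpha * expm1(pmin(x, 0) / spec$alpha)),
    hardshrink = x * (abs(x) > spec$lambda))
}

# Elementwise derivative, given the pre-activation x (used by the trainer).
activation_grad <- function(spec, x) {
  spec <- as_activation(spec)
  switch(spec$name,
    sigmoid = { s <- plogis(x); s * (1 - s) },
    relu = (x > 0) + 0,
    leaky_relu = ifelse(x > 0, 1, spec$leak),
    tanh = 1 - tanh(x)^2,
    softsign = 1 / (1 + abs(x))^2,
    relu6 = (x > 0 & x < 6) + 0,
    celu = ifelse(x > 0, 1, exp(pmin(x, 0) / spec$alpha)),
    hardshrink = (abs(x) > spec$lambda) + 0)
}

#' Analytic range of an activation function
#'
#' @param spec an [activation()] spec (or a name).
#' @return A list with `lower`, `upper` (possibly infinite) and
#'   `covers_negative` (`TRUE` iff the function can output negative
#'   values -- the property that makes tanh, softsign, leaky_relu, celu and
#'   hardshrink candidates for signed flexion targets).
#' @examples
#' activation_range("tanh")   # (-1, 1), covers_negative TRUE
#' activation_range("relu6")  # [0, 6]
#' @export
activation_range <- function(spec) {
  spec <- as_activation(spec)
  r <- switch(spec$name,
    sigmoid = c(0, 1),
    relu = c(0, Inf),
    leaky_relu = c(-Inf, Inf),
    tanh = c(-1, 1),
    softsign = c(-1, 1),
    relu6 = c(0, 6),
    celu = c(-spec$alpha, Inf),
    hardshrink = c(-Inf, Inf))
  list(lower = r[1], upper = r[2], covers_negative = r[1] < 0)
}
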