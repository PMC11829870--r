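test_that("the layer sequence is the fixed 11-layer architecture", {
  spec <- build_bc4d4(62)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_equal(kinds, c("conv1d", "conv1d", "conv1d", "flatten", "dense",
                        "dropout", "dense", "dense", "dense", "dense",
                        "dense"))
  widths <- vapply(spec$layers, `[[`, 1L, "out_width")
  expect_equal(widths[c(1:3, 5, 7:11)],
               c(64L, 128L, 256L, 1024L, 512L, 256L, 128L, 64L, 1L))
  expect_equal(spec$layers[[6]]$rate, 0.1)
  # valid convolutions: length shrinks by 2 each, so flatten = (ip-6)*256
  expect_equal(spec$layers[[4]]$out_width, 56L * 256L)
  expect_equal(build_bc4d4(7)$layers[[4]]$out_width, 256L)
  expect_error(build_bc4d4(6), ">= 7")
})

test_that("parameter counts reproduce the published per-layer ledger", {
  cp <- count_parameters(build_bc4d4(7))
  expect_equal(cp$params[1:3], c(256, 24704, 98560))   # conv 1/64/128 in
  expect_equal(cp$params[4], 0)                        # flatten
  expect_equal(cp$params[6], 0)                        # dropout
  expect_equal(cp$params[7:11], c(524800, 131328, 32896, 8256, 65))
  # first dense: flatten_width * 1024 + 1024 (the printed 262,144 is not
  # consistent with its own product-plus-bias arithmetic)
  expect_equal(cp$params[5], 256 * 1024 + 1024)
  expect_equal(attr(cp, "total"), sum(cp$params))
})

test_that("zero weights give exactly zero output for any input", {
  spec <- build_bc4d4(9)
  w <- rapply(bc4d4:::init_bc4d4(spec, 1), function(m) m * 0,
              how = "replace")
  X <- matrix(rnorm(45), 5, 9)
  expect_equal(bc4d4:::bc4d4_forward(spec, w, X)$output[, 1], rep(0, 5))
})

test_that("bounded heads keep predictions inside (-1, 1)", {
  for (act in c("tanh", "softsign")) {
    spec <- build_bc4d4(8, act)
    w <- bc4d4:::init_bc4d4(spec, 3)
    X <- matrix(rnorm(800, sd = 5), 100, 8)
    out <- bc4d4:::bc4d4_forward(spec, w, X)$output
    expect_true(all(abs(out) < 1))
  }
})

# Straight-line reimplementation of the composed network -- explicit loops
# over the convolution/dense algebra, sharing no code with the package.
naive_forward <- function(x, ip, wval = 0.01) {
  widths <- c(64, 128, 256)
  A <- matrix(x, ncol = 1)              # L x C, one input channel
  for (cout in widths) {
    L <- nrow(A); cin <- ncol(A)
    Z <- matrix(0, L - 2, cout)
    for (t in seq_len(L - 2))
      for (j in seq_len(cout))
        for (k in 1:3)
          for (c in seq_len(cin))
            Z[t, j] <- Z[t, j] + A[t + k - 1, c] * wval
    A <- pmax(Z, 0)                     # ReLU
  }
  a <- as.vector(A)                     # flatten, sample-major
  for (width in c(1024, 512, 256, 128, 64, 1)) {
    z <- numeric(width)
    for (j in seq_len(width)) z[j] <- sum(a * wval)
    a <- tanh(z)
  }
  a
}

test_that("forward pass matches the straight-line oracle to 1e-10", {
  spec <- build_bc4d4(7, "tanh")
  w <- lapply(spec$layers, function(l) {
    if (l$kind == "conv1d")
      list(W = lapply(1:3, function(k)
             matrix(0.01, l$in_width, l$out_width)),
           b = numeric(l$out_width))
    else if (l$kind == "dense")
      list(W = matrix(0.01, l$in_width, l$out_width),
           b = numeric(l$out_width))
    else NULL
  })
  set.seed(17)
  x <- rnorm(7)
  got <- bc4d4:::bc4d4_forward(spec, w, matrix(x, 1), training = FALSE)
  expect_equal(got$output[1, 1], naive_forward(x, 7), tolerance = 1e-10)
})

test_that("evaluation-mode forward is a pure function", {
  spec <- build_bc4d4(8)
  w <- bc4d4:::init_bc4d4(spec, 5)
  X <- matrix(rnorm(80), 10, 8)
  o1 <- bc4d4:::bc4d4_forward(spec, w, X)$output
  o2 <- bc4d4:::bc4d4_forward(spec, w, X)$output
  expect_identical(o1, o2)
})

test_that("training-mode dropout zeroes a Binomial(1024, 0.1) unit count", {
  spec <- build_bc4d4(7)
  w <- bc4d4:::init_bc4d4(spec, 6)
  x <- matrix(rnorm(7), 1)
  set.seed(99)
  zeroed <- replicate(100, {
    fwd <- bc4d4:::bc4d4_forward(spec, w, x, training = TRUE)
    sum(fwd$cache[[6]]$mask == 0)
  })
  # mean of 100 draws from Bin(1024, 0.1): 102.4, sd 9.6/sqrt(100)
  expect_lt(abs(mean(zeroed) - 102.4), 3 * 9.6 / sqrt(100))
})

test_that("gradients match central finite differences", {
  spec <- build_bc4d4(7, "softsign")
  w <- bc4d4:::init_bc4d4(spec, 5)
  X <- matrix(rnorm(28), 4, 7)
  y <- rnorm(4)
  lossf <- function(wts)
    mean((bc4d4:::bc4d4_forward(spec, wts, X)$output[, 1] - y)^2)
  fwd <- bc4d4:::bc4d4_forward(spec, w, X)
  dOut <- matrix(2 * (fwd$output[, 1] - y) / 4, ncol = 1)
  gr <- bc4d4:::bc4d4_backward(spec, w, fwd, dOut)
  eps <- 1e-6
  for (li in c(1, 2, 3, 5, 7, 11)) {
    isconv <- spec$layers[[li]]$kind == "conv1d"
    wt <- w
    if (isconv) {
      g_an <- gr[[li]]$W[[2]][1, 1]
      wt[[li]]$W[[2]][1, 1] <- w[[li]]$W[[2]][1, 1] + eps; lp <- lossf(wt)
      wt[[li]]$W[[2]][1, 1] <- w[[li]]$W[[2]][1, 1] - eps; lm <- lossf(wt)
    } else {
      g_an <- gr[[li]]$W[1, 1]
      wt[[li]]$W[1, 1] <- w[[li]]$W[1, 1] + eps; lp <- lossf(wt)
      wt[[li]]$W[1, 1] <- w[[li]]$W[1, 1] - eps; lm <- lossf(wt)
    }
    g_num <- (lp - lm) / (2 * eps)
    expect_lt(abs(g_an - g_num) / max(1e-10, abs(g_num)), 1e-4)
  }
})

test_that("spec serialization is a readable layer-per-line text form", {
  lines <- serialize_spec(build_bc4d4(62, "softsign"))
  expect_length(lines, 13)   # header (2) + 11 layers
  expect_match(lines[1], "^ip 62$")
  expect_match(lines[3], "conv1d 1 64")
  expect_match(lines[13], "dense 64 1 act=softsign")
  path <- tempfile()
  serialize_spec(build_bc4d4(62, "softsign"), path)
  expect_identical(readLines(path), lines)
  unlink(path)
})
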