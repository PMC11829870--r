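test_that("window counts follow the mode contracts", {
  sim <- tiny_sim()
  w <- make_windows(sim$recording, window_config(), "thumb")
  expect_equal(dim(w$windows), c(2000L, 8L))   # one window per sample
  expect_identical(w$targets, sim$recording$targets[, "thumb"])

  rec100 <- subset_recording(sim$recording, 1:100)
  w2 <- make_windows(rec100, window_config("time_window", ip = 32), 2)
  expect_equal(nrow(w2$windows), floor((100 - 32) / 1) + 1)  # 69
  expect_equal(ncol(w2$windows), 32L)
  # target sits at each window's final sample
  expect_equal(unname(w2$targets[1]), unname(rec100$targets[32, 2]))

  w3 <- make_windows(rec100, window_config("time_window", ip = 32,
                                           stride = 10), 2)
  expect_equal(nrow(w3$windows), floor((100 - 32) / 10) + 1)

  expect_error(make_windows(rec100, window_config("time_window", ip = 200)),
               "exceeds")
  expect_error(make_windows(sim$recording, window_config(), "pinky"),
               "not among")
})

test_that("pearson_r matches hand computation and affine invariance", {
  expect_equal(pearson_r(1:10, 1:10), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  # hand computation: cov 6.5 / sqrt(8.75 * 5)
  expect_equal(pearson_r(c(1, 2, 3, 5), c(1, 2, 3, 4)), 0.9827,
               tolerance = 1e-4)
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50)
  r0 <- pearson_r(x, y)
  expect_lt(abs(pearson_r(3.7 * x + 11, y) - r0), 1e-12)
  expect_lt(abs(pearson_r(x, 0.002 * y - 5) - r0), 1e-12)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_r(1:5, 1:4), "equal length")
})

test_that("training satisfies the smoke and reproducibility contracts", {
  set.seed(10)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- tanh(X %*% rnorm(8) * 0.4)[, 1]
  cfg <- train_config(epochs = 5, batch_size = 64, seed = 2)
  tm <- train_model(build_bc4d4(8), X, y, cfg)
  expect_length(tm$loss_trace, 5)
  expect_true(all(is.finite(tm$loss_trace)))
  expect_lte(tail(tm$loss_trace, 1), tm$loss_trace[1])  # non-divergence
  tm2 <- train_model(build_bc4d4(8), X, y, cfg)
  expect_identical(tm$loss_trace, tm2$loss_trace)
  expect_identical(tm$weights, tm2$weights)
  tm3 <- train_model(build_bc4d4(8), X, y,
                     train_config(epochs = 5, batch_size = 64, seed = 3))
  expect_false(identical(tm$loss_trace, tm3$loss_trace))
  expect_error(train_model(build_bc4d4(9), X, y, cfg), "spec\\$ip")
})

test_that("sgd optimizer also trains without diverging", {
  set.seed(12)
  X <- matrix(rnorm(128 * 8), 128, 8)
  y <- tanh(X %*% rnorm(8) * 0.4)[, 1]
  tm <- train_model(build_bc4d4(8), X, y,
                    train_config(optimizer = "sgd", learning_rate = 0.01,
                                 epochs = 5, batch_size = 64, seed = 2))
  expect_true(all(is.finite(tm$loss_trace)))
  expect_lte(tail(tm$loss_trace, 1), tm$loss_trace[1])
})

test_that("per-finger decoders refuse in-sample evaluation", {
  sim <- tiny_sim(seed = 20)
  split <- split_recording(sim$recording, 0.25)
  models <- fit_decoders(split$train, "tanh", window_config(),
                         train_config(epochs = 1, batch_size = 512,
                                      seed = 1))
  expect_s3_class(models, "bc4d4_decoders")
  expect_named(models, sim$recording$finger_names)
  expect_error(evaluate_decoders(models, split$train), "overlap")
  rep <- evaluate_decoders(models, split$test)
  expect_s3_class(rep, "evaluation_report")
  expect_true(all(rep$per_finger_r >= -1 & rep$per_finger_r <= 1))
  expect_identical(rep$average_r, mean(rep$per_finger_r))
  # the override flag permits diagnostics on training rows
  rep_in <- evaluate_decoders(models, split$train, allow_train_rows = TRUE)
  expect_s3_class(rep_in, "evaluation_report")
})

test_that("degenerate evaluation targets name the offending finger", {
  sim <- tiny_sim(seed = 21)
  split <- split_recording(sim$recording, 0.25)
  models <- fit_decoders(split$train, "tanh", window_config(),
                         train_config(epochs = 1, batch_size = 512,
                                      seed = 1))
  flat <- split$test
  flat$targets[, "index"] <- 0   # zero-variance truth
  expect_error(evaluate_decoders(models, flat), "index")
})

test_that("report CSV mirrors the per-finger table layout", {
  sim <- tiny_sim(seed = 22)
  split <- split_recording(sim$recording, 0.25)
  models <- fit_decoders(split$train, "softsign", window_config(),
                         train_config(epochs = 1, batch_size = 512,
                                      seed = 1))
  rep <- evaluate_decoders(models, split$test)
  path <- tempfile(fileext = ".csv")
  write_report_csv(rep, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("subject", "activation", "thumb", "index",
                             "middle", "ring", "little", "avg"))
  expect_equal(tab$activation, "softsign")
  expect_equal(tab$avg, round(rep$average_r, 4))
  unlink(path)
})

test_that("softsign tracks tanh across seeds on cleaned synthetic data", {
  # directional consistency: over 5 simulated sessions, the mean held-out
  # correlation of the softsign head is within 0.05 of (or above) tanh
  rs <- sapply(1:5, function(s) {
    sim <- simulate_recording(sim_config(
      n_channels = 8, duration_s = 24, sample_rate_hz = 50,
      events_per_finger = 8, coupling_snr = 5, outlier_fraction = 0.02,
      seed = 200 + s))
    cl <- clean_recording(sim$recording,
                          clean_config(0.04, scope = "per_finger"),
                          seed = 200 + s)
    split <- split_recording(cl$recording, 0.2)
    tcfg <- train_config(epochs = 6, batch_size = 256, seed = 300 + s)
    sapply(c("tanh", "softsign"), function(act) {
      m <- fit_decoders(split$train, act, window_config(), tcfg)
      evaluate_decoders(m, split$test)$average_r
    })
  })
  expect_gte(mean(rs["softsign", ]), mean(rs["tanh", ]) - 0.05)
  expect_true(all(rs > 0.5))  # every run decodes far above chance
})
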