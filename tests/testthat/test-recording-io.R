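test_that("zscore_columns standardizes with the population denominator", {
  z <- zscore_columns(c(1, 2, 3))[, 1]
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-7)  # 1.224745
  set.seed(2)
  m <- matrix(rnorm(300, mean = 5, sd = 3), 100, 3)
  z <- zscore_columns(m)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, function(x) mean(x^2)) - 1)), 1e-9)
  # idempotent on standardized input
  expect_equal(zscore_columns(z), z, tolerance = 1e-9)
  expect_error(zscore_columns(cbind(rnorm(5), rep(2, 5))), "column 2")
})

test_that("recording validates alignment and finiteness", {
  expect_error(recording(matrix(0, 5, 2) + 1, matrix(1, 4, 5)),
               "sample counts differ")
  expect_error(recording(matrix(1, 5, 2), matrix(1, 5, 4)), "finger_names")
  bad <- matrix(rnorm(10), 5, 2); bad[2, 1] <- NA
  expect_error(recording(bad, matrix(rnorm(25), 5, 5)), "NaN")
})

test_that("hdf5 round-trip is bit-lossless including truth", {
  sim <- tiny_sim()
  path <- tempfile(fileext = ".h5")
  save_recording(sim$recording, path, truth = sim$truth)
  back <- load_recording(path)
  expect_identical(back$signals, sim$recording$signals)
  expect_identical(back$targets, sim$recording$targets)
  expect_equal(back$sample_rate_hz, sim$recording$sample_rate_hz)
  expect_equal(back$subject_id, sim$recording$subject_id)
  expect_equal(back$finger_names, sim$recording$finger_names)
  truth <- attr(back, "truth")
  expect_identical(truth$clean_targets, sim$truth$clean_targets,
                   ignore_attr = TRUE)
  expect_identical(truth$outlier_mask, sim$truth$outlier_mask,
                   ignore_attr = TRUE)
  unlink(path)
})

test_that("csv round-trip preserves values to 15 significant digits", {
  sim <- tiny_sim()
  path <- tempfile(fileext = ".csv")
  save_recording(sim$recording, path)
  back <- load_recording(path)
  expect_equal(back$signals, sim$recording$signals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$targets, sim$recording$targets, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$finger_names, sim$recording$finger_names)
  expect_equal(back$sample_rate_hz, sim$recording$sample_rate_hz)
  unlink(path)
})

test_that("corrupt files raise format errors, not partial data", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("#subject_id=x", "a,b", "1,2"), path)
  expect_error(load_recording(path), "corrupt|missing")
  unlink(path)
  path2 <- tempfile(fileext = ".h5")
  writeBin(as.raw(1:64), path2)
  expect_error(suppressMessages(load_recording(path2)), "corrupt|HDF5")
  unlink(path2)
  expect_error(load_recording(tempfile(fileext = ".xyz")), "no such file")
  expect_error(save_recording(tiny_sim()$recording,
                              tempfile(fileext = ".xyz")), "format")
})

test_that("MAT reader handles canonical and transposed fixtures", {
  skip_if(python_bin() == "", "no python available")
  set.seed(33)
  sig <- matrix(rnorm(400 * 62), 400, 62)
  dg <- matrix(rnorm(400 * 5), 400, 5)

  path <- tempfile(fileext = ".mat")
  write_mat_fixture(path, list(train_data = sig, train_dg = dg))
  rec <- load_mat_recording(path, "train_data", "train_dg", "s1", 1000)
  expect_equal(dim(rec$signals), c(400L, 62L))
  expect_equal(rec$signals, sig, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rec$targets, dg, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rec$finger_names[1], "thumb")

  # channels x samples storage is auto-transposed
  path_t <- tempfile(fileext = ".mat")
  write_mat_fixture(path_t, list(train_data = t(sig), train_dg = dg))
  rec_t <- load_mat_recording(path_t, "train_data", "train_dg")
  expect_equal(rec_t$signals, sig, tolerance = 1e-12, ignore_attr = TRUE)

  # compressed variables decode identically
  path_c <- tempfile(fileext = ".mat")
  write_mat_fixture(path_c, list(train_data = sig, train_dg = dg),
                    compress = TRUE)
  rec_c <- load_mat_recording(path_c, "train_data", "train_dg")
  expect_equal(rec_c$signals, sig, tolerance = 1e-12, ignore_attr = TRUE)

  # missing variable error lists what the file holds
  expect_error(load_mat_recording(path, "train_data", "nope"),
               "train_data, train_dg")
  unlink(c(path, path_t, path_c))
})

test_that("square signal matrices demand an explicit orientation", {
  skip_if(python_bin() == "", "no python available")
  set.seed(34)
  sig <- matrix(rnorm(25), 5, 5)
  dg <- matrix(rnorm(25), 5, 5)
  path <- tempfile(fileext = ".mat")
  write_mat_fixture(path, list(sig = sig, dg = dg))
  expect_error(load_mat_recording(path, "sig", "dg"), "ambiguous")
  rec <- load_mat_recording(path, "sig", "dg", transpose_signals = TRUE)
  expect_equal(rec$signals, t(sig), tolerance = 1e-12, ignore_attr = TRUE)
  unlink(path)
})

test_that("truncated MAT files raise a format error", {
  skip_if(python_bin() == "", "no python available")
  path <- tempfile(fileext = ".mat")
  write_mat_fixture(path, list(x = matrix(rnorm(100), 10)))
  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".mat")
  writeBin(raw[1:200], trunc_path)
  expect_error(read_mat(trunc_path), "corrupt or truncated")
  writeBin(raw[1:100], trunc_path)
  expect_error(read_mat(trunc_path), "corrupt or truncated|element")
  unlink(c(path, trunc_path))
})

test_that("chronological split partitions samples without overlap", {
  sim <- tiny_sim()
  sp <- split_recording(sim$recording, 0.2)
  expect_equal(n_rows <- nrow(sp$train$signals), 1600)
  expect_equal(nrow(sp$test$signals), 400)
  tr <- attr(sp$train, "row_range")
  te <- attr(sp$test, "row_range")
  expect_length(intersect(tr, te), 0)
  expect_equal(sort(c(tr, te)), 1:2000)
  expect_identical(sp$test$targets[1, ], sim$recording$targets[1601, ])
})
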