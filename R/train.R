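#' Windowing configuration
#'
#' Two ways to present a recording to the network. In
#' `"channels_as_sequence"` mode (the default and the one matching the
#' published layer table, whose input shape is the per-sample feature
#' vector), each sample's channel vector is one window, so `ip` equals the
#' channel count and each window's target is that sample's finger value.
#' In `"time_window"` mode, windows are contiguous runs of `ip` samples of
#' a single channel (or the channel average), with the target taken at the
#' window's final sample.
#'
#' @param mode `"channels_as_sequence"` or `"time_window"`.
#' @param ip window length; ignored (set to the channel count) in
#'   channels-as-sequence mode; default 32 in time-window mode.
#' @param stride step between window starts in time-window mode
#'   (default 1).
#' @param channel channel index, or `"all-averaged"` to average channels,
#'   in time-window mode.
#' @return A list of class `"window_config"`.
#' @export
window_config <- function(mode = c("channels_as_sequence", "time_window"),
                          ip = 32L, stride = 1L, channel = "all-averaged") {
  mode <- match.arg(mode)
  check_scalar_number(ip, "ip", 7, integer = TRUE)
  check_scalar_number(stride, "stride", 1, integer = TRUE)
  structure(list(mode = mode, ip = as.integer(ip),
                 stride = as.integer(stride), channel = channel),
            class = "window_config")
}

#' Cut a recording into model input windows for one finger
#'
#' @param rec a [recording()].
#' @param cfg a [window_config()].
#' @param finger finger name or index.
#' @return A list with `windows` (n x ip matrix) and `targets` (length-n
#'   vector). In channels-as-sequence mode there is one window per sample;
#'   in time-window mode there are
#'   `floor((samples - ip) / stride) + 1` windows.
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 5, n_channels = 8))
#' w <- make_windows(sim$recording, window_config(), "thumb")
#' dim(w$windows)  # 500 x 8
#' @export
make_windows <- function(rec, cfg = window_config(), finger = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (!inherits(cfg, "window_config")) cfg <- do.call(window_config, cfg)
  if (is.character(finger)) {
    f <- match(finger, rec$finger_names)
    if (is.na(f)) stop_field("finger", sprintf(
      "'%s' not among: %s", finger, paste(rec$finger_names, collapse = ", ")))
  } else f <- as.integer(finger)
  if (f < 1L || f > ncol(rec$targets)) stop_field("finger", "out of range")
  y <- rec$targets[, f]
  if (cfg$mode == "channels_as_sequence") {
    if (ncol(rec$signals) < 7L)
      stop_field("rec", "channels-as-sequence windows need >= 7 channels")
    return(list(windows = rec$signals, targets = y))
  }
  trace <- if (identical(cfg$channel, "all-averaged")) rowMeans(rec$signals)
           else rec$signals[, as.integer(cfg$channel)]
  n <- length(trace)
  if (cfg$ip > n)
    stop_field("ip", sprintf("window length %d exceeds %d samples",
                             cfg$ip, n))
  starts <- seq.int(1L, n - cfg$ip + 1L, by = cfg$stride)
  windows <- t(vapply(starts, function(s) trace[s:(s + cfg$ip - 1L)],
                      numeric(cfg$ip)))
  list(windows = windows, targets = y[starts + cfg$ip - 1L])
}

#' Training configuration
#'
#' The published description of the decoder states no optimizer, loss,
#' epoch count or split; these defaults are ordinary deep-learning practice
#' and every value is echoed into reports for provenance.
#'
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param learning_rate step size (default 1e-3).
#' @param epochs passes over the training windows (default 50).
#' @param batch_size minibatch size (default 256).
#' @param loss only `"mse"`.
#' @param l2 L2 weight-decay coefficient (default 0, i.e. off).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param test_fraction chronological tail held out by the high-level
#'   drivers (default 0.2).
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 1e-3,
                         epochs = 50L, batch_size = 256L, loss = "mse",
                         l2 = 0, seed = 1L, test_fraction = 0.2) {
  optimizer <- match.arg(optimizer)
  check_scalar_number(learning_rate, "learning_rate", 0, open_lower = TRUE)
  check_scalar_number(epochs, "epochs", 1, integer = TRUE)
  check_scalar_number(batch_size, "batch_size", 1, integer = TRUE)
  stopifnot(identical(loss, "mse"))
  check_scalar_number(l2, "l2", 0)
  check_scalar_number(seed, "seed", integer = TRUE)
  check_scalar_number(test_fraction, "test_fraction", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss, l2 = l2,
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "train_config")
}

# One optimizer step over the nested weight list. Updates are performed
# in place (C++): the weight buffers are private to train_model, which
# created them itself, so no user-visible object is mutated.
.optim_step <- function(weights, grads, state, cfg, step) {
  upd <- function(w, g, s) {
    if (cfg$optimizer == "sgd") {
      .sgd_step_inplace(w, g, cfg$learning_rate, cfg$l2)
      return(FALSE)  # placeholder: assigning NULL would shrink the list
    }
    if (is.null(s)) s <- list(m = numeric(length(w)),
                              v = numeric(length(w)))
    .adam_step_inplace(w, g, s$m, s$v, cfg$learning_rate, 0.9, 0.999,
                       1e-8, step, cfg$l2)
    s
  }
  for (i in seq_along(weights)) {
    if (is.null(weights[[i]])) next
    if (is.null(state[[i]]))
      state[[i]] <- stats::setNames(vector("list", length(weights[[i]])),
                                    names(weights[[i]]))
    for (nm in names(weights[[i]])) {
      w <- weights[[i]][[nm]]
      if (is.list(w)) {  # conv kernels: list of matrices
        if (is.null(state[[i]][[nm]]))
          state[[i]][[nm]] <- vector("list", length(w))
        for (k in seq_along(w))
          state[[i]][[nm]][[k]] <- upd(w[[k]], grads[[i]][[nm]][[k]],
                                       state[[i]][[nm]][[k]])
      } else {
        state[[i]][[nm]] <- upd(w, grads[[i]][[nm]], state[[i]][[nm]])
      }
    }
  }
  state
}

#' Train a BC4D4 model on prepared windows
#'
#' Minibatch gradient descent (Adam by default) on mean-squared error,
#' with dropout active during training only. Fully reproducible from
#' `cfg$seed`: initialization, shuffling and dropout masks all come from
#' one stream, so two runs with the same seed produce identical loss
#' traces and weights.
#'
#' @param spec a [build_bc4d4()] specification (its `ip` must match
#'   `ncol(windows)`).
#' @param windows n x ip input matrix from [make_windows()].
#' @param targets length-n numeric target vector.
#' @param cfg a [train_config()].
#' @return An object of class `"bc4d4_trained"`: the spec, learned weights,
#'   config, per-epoch training-loss trace, and the provenance of the
#'   training rows (attribute `"train_rows"` when the windows came from a
#'   [split_recording()] segment).
#' @export
train_model <- function(spec, windows, targets, cfg = train_config()) {
  stopifnot(inherits(spec, "bc4d4_spec"))
  if (!inherits(cfg, "train_config")) cfg <- do.call(train_config, cfg)
  windows <- as.matrix(windows)
  if (ncol(windows) != spec$ip)
    stop_field("windows", sprintf("have %d columns but spec$ip = %d",
                                  ncol(windows), spec$ip))
  if (length(targets) != nrow(windows))
    stop_field("targets", "length must equal nrow(windows)")
  n <- nrow(windows)
  with_local_seed(cfg$seed, {
    weights <- init_bc4d4(spec, seed = sample.int(.Machine$integer.max, 1))
    state <- vector("list", length(weights))
    loss_trace <- numeric(cfg$epochs)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        Xb <- windows[idx, , drop = FALSE]
        yb <- targets[idx]
        fwd <- bc4d4_forward(spec, weights, Xb, training = TRUE)
        resid <- fwd$output[, 1] - yb
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("training diverged to a non-finite loss; lower ",
               "`learning_rate` (current ", cfg$learning_rate, ")",
               call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
        dOut <- matrix(2 * resid / length(idx), ncol = 1L)
        grads <- bc4d4_backward(spec, weights, fwd, dOut)
        step <- step + 1L
        state <- .optim_step(weights, grads, state, cfg, step)
      }
      loss_trace[ep] <- ep_loss / n
    }
    structure(list(spec = spec, weights = weights, config = cfg,
                   loss_trace = loss_trace),
              class = "bc4d4_trained")
  })
}

#' @export
predict.bc4d4_trained <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  bc4d4_forward(object$spec, object$weights, newdata,
                training = FALSE)$output[, 1]
}

#' Pearson product-moment correlation
#'
#' The field's standard decoding metric for this dataset: correlation
#' between predicted and true flexion on held-out data.
#'
#' @param pred,truth equal-length numeric vectors (length >= 2), each with
#'   nonzero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 5), c(1, 2, 3, 4))  # 0.9827
#' @export
pearson_r <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2L)
    stop_field("pred", "pred and truth must have equal length >= 2")
  if (anyNA(pred) || anyNA(truth))
    stop_field("pred", "inputs must be finite")
  if (var(pred) == 0)
    stop_field("pred", "has zero variance; correlation undefined")
  if (var(truth) == 0)
    stop_field("truth", "has zero variance; correlation undefined")
  cor(pred, truth)
}

#' Train one decoder per finger
#'
#' Trains an independent BC4D4 network for every finger (the architecture
#' has a single output unit; per-finger models are how the per-finger
#' correlation tables arise) on the chronological training segment.
#'
#' @param train_rec training segment [recording()] (from
#'   [split_recording()]).
#' @param dense_activation `"tanh"` or `"softsign"`.
#' @param wcfg a [window_config()].
#' @param tcfg a [train_config()]; model `f` uses `tcfg$seed + f - 1`.
#' @return A named list (one [train_model()] result per finger) of class
#'   `"bc4d4_decoders"`, carrying the training-row provenance.
#' @export
fit_decoders <- function(train_rec, dense_activation = "tanh",
                         wcfg = window_config(), tcfg = train_config()) {
  stopifnot(inherits(train_rec, "recording"))
  ip <- if (wcfg$mode == "channels_as_sequence") ncol(train_rec$signals)
        else wcfg$ip
  models <- lapply(seq_along(train_rec$finger_names), function(f) {
    spec <- build_bc4d4(ip, dense_activation)
    w <- make_windows(train_rec, wcfg, f)
    cfg_f <- tcfg
    cfg_f$seed <- tcfg$seed + f - 1L
    train_model(spec, w$windows, w$targets, cfg_f)
  })
  names(models) <- train_rec$finger_names
  structure(models, class = "bc4d4_decoders",
            train_rows = attr(train_rec, "row_range", exact = TRUE),
            subject_id = train_rec$subject_id,
            activation = dense_activation, window_config = wcfg)
}

#' Evaluate per-finger decoders on a held-out recording segment
#'
#' Computes the Pearson correlation between each finger model's
#' predictions and the true flexion on the evaluation segment, plus the
#' five-finger average -- the per-finger report layout of the published
#' correlation tables. Refuses to evaluate on rows the decoders were
#' trained on unless explicitly overridden, since in-sample correlations
#' overstate decoding performance.
#'
#' @param models a [fit_decoders()] result.
#' @param rec evaluation [recording()] segment.
#' @param allow_train_rows set `TRUE` to bypass the train/test overlap
#'   check (for diagnostics only).
#' @return A list of class `"evaluation_report"` with `per_finger_r`
#'   (named vector), `average_r`, `subject_id`, `activation` and the
#'   embedded window/training configs.
#' @export
evaluate_decoders <- function(models, rec, allow_train_rows = FALSE) {
  stopifnot(inherits(models, "bc4d4_decoders"), inherits(rec, "recording"))
  train_rows <- attr(models, "train_rows", exact = TRUE)
  rec_rows <- attr(rec, "row_range", exact = TRUE)
  if (!allow_train_rows && !is.null(train_rows) && !is.null(rec_rows) &&
      length(intersect(train_rows, rec_rows)) > 0L)
    stop("evaluation rows overlap the training segment; pass ",
         "`allow_train_rows = TRUE` only for diagnostics", call. = FALSE)
  wcfg <- attr(models, "window_config", exact = TRUE)
  rs <- vapply(seq_along(models), function(f) {
    w <- make_windows(rec, wcfg, f)
    pred <- predict(models[[f]], w$windows)
    tryCatch(pearson_r(pred, w$targets),
             error = function(e) stop(sprintf("finger '%s': %s",
                                              names(models)[f],
                                              conditionMessage(e)),
                                      call. = FALSE))
  }, numeric(1))
  names(rs) <- names(models)
  structure(list(per_finger_r = rs, average_r = mean(rs),
                 subject_id = attr(models, "subject_id", exact = TRUE),
                 activation = attr(models, "activation", exact = TRUE),
                 window_config = wcfg,
                 train_config = models[[1]]$config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> subject %s, %s head\n", x$subject_id,
              x$activation))
  print(round(c(x$per_finger_r, avg = x$average_r), 4))
  invisible(x)
}

#' Write evaluation reports as a CSV in the per-finger table layout
#'
#' Columns: subject, activation, one column per finger, avg -- one row per
#' report, the layout of the published per-finger correlation tables.
#'
#' @param reports one [evaluate_decoders()] report or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  rows <- lapply(reports, function(r)
    data.frame(subject = r$subject_id, activation = r$activation,
               as.list(round(r$per_finger_r, 4)),
               avg = round(r$average_r, 4), check.names = FALSE))
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
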