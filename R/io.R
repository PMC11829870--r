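#' Save a recording to HDF5 or CSV
#'
#' HDF5 layout: datasets `signals` and `targets`, root attributes
#' `sample_rate_hz`, `subject_id` and `finger_names`, and (optionally) a
#' `truth` group holding the simulator's `clean_targets`, `outlier_mask`
#' and `mixing`. The HDF5 round-trip is bit-lossless. The CSV form is a
#' single file with `#key=value` metadata comment lines followed by a
#' header `chan_1,...,thumb,...`; numeric round-trip is lossless to 15
#' significant digits.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param format `"hdf5"` or `"csv"`; default inferred from the extension
#'   (`.h5`/`.hdf5` vs `.csv`).
#' @param truth optional `sim_truth` from [simulate_recording()], stored
#'   alongside (HDF5 only).
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path, format = NULL, truth = NULL) {
  stopifnot(inherits(rec, "recording"))
  format <- format %||% infer_format(path)
  if (format == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(rec$signals, path, "signals")
    rhdf5::h5write(rec$targets, path, "targets")
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid), add = TRUE)
    rhdf5::h5writeAttribute(rec$sample_rate_hz, fid, "sample_rate_hz")
    rhdf5::h5writeAttribute(rec$subject_id, fid, "subject_id")
    rhdf5::h5writeAttribute(rec$finger_names, fid, "finger_names")
    if (!is.null(truth)) {
      rhdf5::h5createGroup(fid, "truth")
      rhdf5::h5write(truth$clean_targets, fid, "truth/clean_targets")
      rhdf5::h5write(truth$outlier_mask + 0L, fid, "truth/outlier_mask")
      rhdf5::h5write(truth$mixing, fid, "truth/mixing")
    }
  } else if (format == "csv") {
    meta <- c(sprintf("#sample_rate_hz=%s", format(rec$sample_rate_hz,
                                                   digits = 15)),
              sprintf("#subject_id=%s", rec$subject_id),
              sprintf("#finger_names=%s",
                      paste(rec$finger_names, collapse = ";")),
              sprintf("#n_channels=%d", ncol(rec$signals)))
    writeLines(meta, path)
    df <- data.frame(rec$signals, rec$targets, check.names = FALSE)
    names(df) <- c(sprintf("chan_%d", seq_len(ncol(rec$signals))),
                   rec$finger_names)
    data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  } else stop_field("format", "must be 'hdf5' or 'csv'")
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, h5 = , hdf5 = "hdf5", csv = "csv",
         stop_field("path", sprintf(
           "cannot infer format from extension '.%s'; pass `format`", ext)))
}

#' Load a recording saved by [save_recording()]
#'
#' @param path file path (`.h5`/`.hdf5` or `.csv`).
#' @param format override the extension-based format inference.
#' @return A [recording()]; for HDF5 files written with a `truth` group,
#'   the truth is re-attached as attribute `"truth"`.
#' @export
load_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  format <- format %||% infer_format(path)
  if (format == "hdf5") {
    contents <- tryCatch(rhdf5::h5ls(path),
                         error = function(e) stop("corrupt or truncated ",
                                                  "HDF5 file: ", path,
                                                  call. = FALSE))
    signals <- rhdf5::h5read(path, "signals")
    targets <- rhdf5::h5read(path, "targets")
    fid <- rhdf5::H5Fopen(path)
    rate <- as.numeric(rhdf5::h5readAttributes(fid, "/")$sample_rate_hz)
    subject <- as.character(rhdf5::h5readAttributes(fid, "/")$subject_id)
    fingers <- as.character(rhdf5::h5readAttributes(fid, "/")$finger_names)
    rhdf5::H5Fclose(fid)
    rec <- recording(signals, targets, rate, subject, fingers)
    if ("truth" %in% contents$name) {
      truth <- list(
        clean_targets = rhdf5::h5read(path, "truth/clean_targets"),
        outlier_mask = rhdf5::h5read(path, "truth/outlier_mask") > 0L,
        mixing = rhdf5::h5read(path, "truth/mixing"))
      attr(rec, "truth") <- truth
    }
    rec
  } else if (format == "csv") {
    lines <- readLines(path, n = 10L)
    meta_lines <- grep("^#", lines, value = TRUE)
    meta <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
    kv <- stats::setNames(vapply(meta, function(p)
      paste(p[-1], collapse = "="), ""), vapply(meta, `[[`, "", 1L))
    for (key in c("n_channels", "finger_names"))
      if (!key %in% names(kv))
        stop("corrupt or truncated recording CSV: missing #", key,
             " metadata in ", path, call. = FALSE)
    dt <- data.table::fread(path, skip = length(meta_lines),
                            header = TRUE, data.table = FALSE)
    n_chan <- as.integer(kv[["n_channels"]])
    fingers <- strsplit(kv[["finger_names"]], ";", fixed = TRUE)[[1]]
    if (ncol(dt) != n_chan + length(fingers))
      stop("corrupt or truncated recording CSV: expected ",
           n_chan + length(fingers), " columns, found ", ncol(dt),
           call. = FALSE)
    recording(as.matrix(dt[, seq_len(n_chan), drop = FALSE]),
              as.matrix(dt[, n_chan + seq_along(fingers), drop = FALSE]),
              as.numeric(kv[["sample_rate_hz"]]), kv[["subject_id"]],
              fingers)
  } else stop_field("format", "must be 'hdf5' or 'csv'")
}

#' Load a recording from a MATLAB level-5 MAT-file
#'
#' The competition distributes recordings as MAT-files; this reads the two
#' named 2-D numeric variables and normalizes them to the canonical
#' samples-on-first-axis orientation. Orientation is inferred by matching
#' axes between the two variables: the targets' sample axis is the longer
#' one, and the signals are transposed if their sample count sits on the
#' second axis. When both axes are ambiguous (square matrices), an
#' explicit `transpose_signals` flag is required rather than guessing.
#'
#' @param path MAT-file path.
#' @param signal_var,target_var names of the signal and dataglove variables
#'   inside the file (the competition files carry no canonical names, so
#'   both are required).
#' @param subject_id label for the returned recording.
#' @param sample_rate_hz optional sampling rate metadata.
#' @param transpose_signals `NA` (infer), or `TRUE`/`FALSE` to force.
#' @return A [recording()].
#' @export
load_mat_recording <- function(path, signal_var, target_var,
                               subject_id = "unknown",
                               sample_rate_hz = NA_real_,
                               transpose_signals = NA) {
  vars <- read_mat(path)
  for (v in c(signal_var, target_var))
    if (!v %in% names(vars))
      stop(sprintf("variable '%s' not found; file contains: %s", v,
                   paste(names(vars), collapse = ", ")), call. = FALSE)
  S <- vars[[signal_var]]
  Tm <- vars[[target_var]]
  for (nm in c(signal_var, target_var)) {
    m <- vars[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      stop(sprintf("variable '%s' is not a 2-D numeric matrix", nm),
           call. = FALSE)
  }
  # targets: the sample axis is the longer one (fingers number ~5)
  if (nrow(Tm) < ncol(Tm)) Tm <- t(Tm)
  n <- nrow(Tm)
  if (is.na(transpose_signals)) {
    if (nrow(S) == n && ncol(S) == n)
      stop("signal matrix is square; orientation is ambiguous -- pass ",
           "`transpose_signals` explicitly", call. = FALSE)
    if (nrow(S) == n) transpose_signals <- FALSE
    else if (ncol(S) == n) transpose_signals <- TRUE
    else stop(sprintf(
      "no axis of '%s' (%d x %d) matches the %d samples of '%s'",
      signal_var, nrow(S), ncol(S), n, target_var), call. = FALSE)
  }
  if (transpose_signals) S <- t(S)
  fingers <- c("thumb", "index", "middle", "ring", "little")
  if (ncol(Tm) != 5L) fingers <- sprintf("finger%d", seq_len(ncol(Tm)))
  recording(S, Tm, sample_rate_hz, subject_id, fingers)
}
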