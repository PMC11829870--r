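# Small shared fixtures, all generated in code.

# A quick low-cost simulated recording (2,000 samples, 8 channels).
tiny_sim <- function(seed = 42, ...) {
  args <- modifyList(list(n_channels = 8, duration_s = 20,
                          sample_rate_hz = 100, events_per_finger = 6,
                          seed = seed), list(...))
  simulate_recording(do.call(sim_config, args))
}

# Path of the python interpreter used for cross-implementation oracles.
python_bin <- function() Sys.which("python")

run_python <- function(code) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  out <- system2(python_bin(), script, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")))
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}

# Write a MAT-5 file with scipy (the independent writer for reader tests).
write_mat_fixture <- function(path, vars, compress = FALSE) {
  data_dir <- tempfile()
  dir.create(data_dir)
  on.exit(unlink(data_dir, recursive = TRUE))
  csvs <- vapply(names(vars), function(nm) {
    p <- file.path(data_dir, paste0(nm, ".csv"))
    write.table(vars[[nm]], p, row.names = FALSE, col.names = FALSE,
                sep = ",")
    p
  }, "")
  run_python(c(
    "import numpy as np, scipy.io",
    sprintf("names = %s", py_str_list(names(vars))),
    sprintf("paths = %s", py_str_list(unname(csvs))),
    "mdict = {n: np.loadtxt(p, delimiter=',', ndmin=2) for n, p in zip(names, paths)}",
    sprintf("scipy.io.savemat(%s, mdict, do_compression=%s)",
            py_str(path), if (compress) "True" else "False")))
  path
}

py_str <- function(x) paste0("r'", x, "'")
py_str_list <- function(xs) paste0("[", paste(py_str(xs), collapse = ", "), "]")
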