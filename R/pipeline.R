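pipeline_sections <- function() list(
  run      = c("run_id", "output_dir"),
  simulate = names(formals(sim_config)),
  clean    = c(names(formals(clean_config)), "seed", "n_trees", "psi"),
  window   = names(formals(window_config)),
  train    = names(formals(train_config)),
  activation = c("name", "alpha", "lambda", "leak"))

#' Read and validate a pipeline configuration file
#'
#' Plain-text, TOML-like `[section]` / `key = value` format (sections:
#' `run`, `simulate`, `clean`, `window`, `train`, `activation`). Every key
#' must belong to its section's owning constructor; unknown sections or
#' keys are rejected before anything runs, and each section is validated
#' by the module that owns it (so e.g. a contamination of 1.2 fails
#' naming `clean.contamination`). There are no hidden defaults: the
#' resolved value of every parameter is echoed into the run manifest.
#'
#' @param path config file path.
#' @return A validated nested list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  sections <- pipeline_sections()
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(sections))
        stop_field(section, paste("unknown section; expected one of:",
                                  paste(names(sections),
                                        collapse = ", ")))
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section))
        stop("config line before any [section]: ", ln, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% sections[[section]])
        stop_field(paste0(section, ".", key), "unknown key")
      val <- utils::type.convert(gsub("^\"|\"$", "", val), as.is = TRUE)
      cfg[[section]][[key]] <- val
    } else stop("unparseable config line: ", ln, call. = FALSE)
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  wrap <- function(section, builder) {
    args <- cfg[[section]] %||% list()
    tryCatch(do.call(builder, args),
             error = function(e) stop(sprintf(
               "section [%s]: %s", section, conditionMessage(e)),
               call. = FALSE))
  }
  out <- list(
    run = modifyList(list(run_id = "run", output_dir = "bc4d4-run"),
                     cfg$run %||% list()),
    simulate = wrap("simulate", sim_config),
    clean = wrap("clean", function(contamination = 0.70, scope = "joint",
                                   re_zscore = FALSE, seed = 1L,
                                   n_trees = 100L, psi = 256L) {
      ccfg <- tryCatch(
        clean_config(contamination, scope, re_zscore),
        error = function(e) stop(sub("`contamination`",
                                     "`clean.contamination`",
                                     conditionMessage(e)), call. = FALSE))
      c(ccfg, list(seed = seed, n_trees = n_trees, psi = psi))
    }),
    window = wrap("window", window_config),
    train = wrap("train", train_config),
    activation = do.call(activation,
                         modifyList(list(name = "tanh"),
                                    cfg$activation %||% list())))
  structure(out, class = "pipeline_config")
}

# md5 of an object's serialized content (not of file bytes, which for
# container formats can differ across writes of identical data).
content_md5 <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(obj, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate -> profile -> clean -> train -> evaluate pipeline
#'
#' Executes the five stages in order inside `output_dir`, checksumming each
#' stage's outputs; a rerun with the same config file reproduces identical
#' checksums for the deterministic stages. Any stage failure aborts with
#' the stage name while earlier artifacts are preserved.
#'
#' @param config a [read_pipeline_config()] result or a config file path.
#' @return The run manifest (also written as `manifest.json`): per-stage
#'   artifact paths and content checksums plus a full echo of the resolved
#'   configuration.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  dir.create(config$run$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$run$output_dir, name)
  stages <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages[[name]] <<- res
    res
  }

  run_stage("simulate", function() {
    sim <- simulate_recording(config$simulate)
    save_recording(sim$recording, out("recording.h5"), truth = sim$truth)
    list(outputs = c(recording = out("recording.h5")),
         checksums = c(recording = content_md5(sim$recording[1:2])),
         rows = n_samples(sim$recording))
    })
  rec <- load_recording(out("recording.h5"))

  run_stage("profile", function() {
    desc <- describe(rec, "targets")
    write_describe_csv(desc, out("stats_raw.csv"))
    list(outputs = c(stats = out("stats_raw.csv")),
         checksums = c(stats = content_md5(desc)))
  })

  ccfg <- clean_config(config$clean$contamination, config$clean$scope,
                       config$clean$re_zscore)
  run_stage("clean", function() {
    cl <- clean_recording(rec, ccfg, seed = config$clean$seed,
                          n_trees = config$clean$n_trees,
                          psi = config$clean$psi)
    save_recording(cl$recording, out("clean.h5"))
    data.table::fwrite(data.frame(row = seq_along(cl$kept),
                                  kept = cl$kept), out("mask.csv"))
    write_describe_csv(describe(cl$recording, "targets"),
                       out("stats_clean.csv"))
    list(outputs = c(recording = out("clean.h5"), mask = out("mask.csv"),
                     stats = out("stats_clean.csv")),
         checksums = c(recording = content_md5(cl$recording[1:2]),
                       mask = content_md5(cl$kept)),
         rows_in = n_samples(rec), rows_out = n_samples(cl$recording))
  })
  clean_rec <- load_recording(out("clean.h5"))

  split <- split_recording(clean_rec, config$train$test_fraction)
  models <- run_stage("train", function() {
    m <- fit_decoders(split$train, config$activation$name,
                      config$window, config$train)
    saveRDS(m, out("models.rds"))
    list(models = m,
         outputs = c(models = out("models.rds")),
         checksums = c(models = content_md5(lapply(m, `[[`, "weights"))),
         n_params = attr(count_parameters(m[[1]]$spec), "total"),
         epochs = config$train$epochs)
  })$models

  run_stage("evaluate", function() {
    report <- evaluate_decoders(models, split$test)
    write_report_csv(report, out("report.csv"))
    list(outputs = c(report = out("report.csv")),
         checksums = c(report = content_md5(report$per_finger_r)),
         average_r = report$average_r)
  })

  manifest <- list(run_id = config$run$run_id,
                   output_dir = config$run$output_dir,
                   config = lapply(unclass(config), function(s)
                     lapply(unclass(s), unclass)),
                   stages = lapply(stages, function(s)
                     s[setdiff(names(s), "models")]))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("pipeline '%s': %d stages complete; manifest at %s",
                  config$run$run_id, length(stages), out("manifest.json")))
  invisible(manifest)
}
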