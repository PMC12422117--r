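# End-to-end pipeline driver: simulate -> preprocess -> deconvolve -> train
# -> evaluate, with a JSON-configurable entry point, artifact manifest and
# data-directory validation.

PIPELINE_KEYS <- c("cohort", "preprocessing", "deconvolution", "model",
                   "training", "split", "out_dir", "log_level")

#' Build a validated pipeline configuration
#'
#' Assembles and validates the configuration of a full run. Unknown keys are
#' rejected before any stage executes.
#'
#' @param cohort a [cohort_spec()] or a list of its arguments.
#' @param preprocessing list: `plateau_fraction`, `variance_target`.
#' @param deconvolution list: `n_components`.
#' @param model an [adena_config()] or a list of its arguments.
#' @param training a [train_config()] or a list of its arguments.
#' @param split a [split_spec()] or a list of its arguments.
#' @param out_dir output directory for artifacts.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(n_asthmatic = 20, n_control = 25),
                            preprocessing = list(), deconvolution = list(),
                            model = list(), training = list(), split = list(),
                            out_dir = tempfile("breathdx_run_"),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!inherits(cohort, "breathdx_cohort_spec"))
    cohort <- do.call(cohort_spec, cohort)
  if (!inherits(model, "adena_config")) model <- do.call(adena_config, model)
  if (!inherits(training, "train_config"))
    training <- do.call(train_config, training)
  if (!inherits(split, "split_spec")) split <- do.call(split_spec, split)
  pre_known <- c("plateau_fraction", "variance_target")
  assert_that(all(names(preprocessing) %in% pre_known),
              paste("unknown preprocessing key(s):",
                    paste(setdiff(names(preprocessing), pre_known),
                          collapse = ", ")))
  dec_known <- c("n_components")
  assert_that(all(names(deconvolution) %in% dec_known),
              paste("unknown deconvolution key(s):",
                    paste(setdiff(names(deconvolution), dec_known),
                          collapse = ", ")))
  structure(list(cohort = cohort,
                 preprocessing = utils::modifyList(
                   list(plateau_fraction = 0.5, variance_target = 0.95),
                   preprocessing),
                 deconvolution = utils::modifyList(
                   list(n_components = 3L), deconvolution),
                 model = model, training = training, split = split,
                 out_dir = out_dir, log_level = log_level),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Reads a JSON file whose top-level keys mirror the [pipeline_config()]
#' arguments; unknown keys are rejected before any stage runs.
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  assert_that(length(unknown) == 0,
              paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

pipe_log <- function(cfg, ...) {
  if (cfg$log_level == "info") message("[breathdx] ", ...)
}

#' Run the full diagnostic pipeline
#'
#' Executes, in order: cohort simulation, feature extraction,
#' standardization + PCA, VOC deconvolution with group comparison, a
#' subject-level train/validation/test split, ADENA training on the
#' train+validation pool, and a final evaluation on the held-out test
#' subjects. Every artifact is written under `config$out_dir` and recorded
#' in the returned manifest together with its MD5 checksum; rerunning the
#' same configuration reproduces the checksums of the deterministic
#' artifacts.
#'
#' @param config a [pipeline_config()] (or a JSON path accepted by
#'   [read_pipeline_config()]).
#' @return the run manifest (list): `artifacts` (paths), `checksums`,
#'   `seed`, `stages_completed`, `failed_stage` (NULL on success),
#'   `test_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(artifacts = list(), checksums = list(),
                   seed = config$cohort$seed, stages_completed = character(0),
                   failed_stage = NULL, test_report = NULL)
  record <- function(name, path) {
    manifest$artifacts[[name]] <<- path
    manifest$checksums[[name]] <<- unname(tools::md5sum(path))
  }
  stage <- function(name, fun) {
    if (!is.null(manifest$failed_stage)) return(NULL)
    out <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(manifest$failed_stage))
      manifest$stages_completed <<- c(manifest$stages_completed, name)
    out
  }

  cohort <- stage("simulate", function() {
    pipe_log(config, "simulating cohort (seed ", config$cohort$seed, ")")
    ch <- generate_cohort(config$cohort)
    paths <- write_cohort(ch, file.path(config$out_dir, "cohort"))
    record("cohort_csv", paths[["waveforms"]])
    record("cohort_json", paths[["metadata"]])
    ch
  })

  features <- stage("features", function() {
    ft <- extract_feature_table(
      cohort, plateau_fraction = config$preprocessing$plateau_fraction)
    path <- file.path(config$out_dir, "features.csv")
    write_feature_table(ft, path)
    record("features_csv", path)
    ft
  })

  stage("pca", function() {
    cols <- feature_columns(features)
    X <- suppressWarnings(standardize(features[, cols]))
    pca <- fit_pca(X, variance_target = config$preprocessing$variance_target)
    path <- file.path(config$out_dir, "pca.json")
    write_pca(pca, path)
    record("pca_json", path)
    pca
  })

  stage("deconvolve", function() {
    res <- list(asthmatic = list(), control = list())
    for (rec in cohort) {
      if (rec$replicate_index != 1L) next
      x <- seq(0, rec$retention_span,
               length.out = length(rec$channels$voc_total))
      fit <- deconvolve(rec$channels$voc_total,
                        n_components = config$deconvolution$n_components,
                        x = x)
      cl <- if (rec$label == 1L) "asthmatic" else "control"
      res[[cl]][[length(res[[cl]]) + 1L]] <- fit
    }
    cmp <- compare_groups(res)
    paths <- write_comparison(cmp, file.path(config$out_dir, "deconvolution"))
    record("deconv_components_csv", paths[["components"]])
    record("deconv_percent_csv", paths[["percent_differences"]])
    cmp
  })

  fit_and_report <- stage("train", function() {
    parts <- split_dataset(features$subject_id, features$label, config$split)
    pool <- !(features$subject_id %in% parts$test)
    cols <- feature_columns(features)
    prep <- prepare_fold_features(
      features[pool, cols], features[!pool, cols],
      config$preprocessing$variance_target)
    fit <- adena_train(prep$train, features$label[pool],
                       model_config = config$model, config = config$training)
    hist_path <- file.path(config$out_dir, "history.csv")
    utils::write.csv(fit$history, hist_path, row.names = FALSE)
    record("history_csv", hist_path)
    w_path <- file.path(config$out_dir, "weights.json")
    jsonlite::write_json(
      lapply(fit$model$weights, function(w) {
        if (is.matrix(w) || is.array(w)) list(dim = dim(w), data = as.numeric(w))
        else list(dim = length(w), data = as.numeric(w))
      }), w_path, digits = NA, auto_unbox = FALSE)
    record("weights_json", w_path)
    p <- adena_predict(fit, prep$test)
    rep <- eval_report(features$label[!pool], p)
    rep_path <- file.path(config$out_dir, "eval_report.json")
    write_eval_report(rep, rep_path)
    record("eval_report_json", rep_path)
    rep
  })
  manifest$test_report <- fit_and_report

  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(artifacts = manifest$artifacts, checksums = manifest$checksums,
         seed = manifest$seed, stages_completed = manifest$stages_completed,
         failed_stage = manifest$failed_stage),
    man_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest$manifest_path <- man_path
  manifest
}

#' Validate a simulated data directory
#'
#' Checks that a directory written by [write_cohort()] is structurally
#' sound: readable CSV/JSON, all 13 canonical channels present for every
#' record, equal channel lengths, finite values, and a label for every
#' subject. Violations are listed, one row each, located by subject,
#' replicate and channel.
#'
#' @param path directory containing `waveforms.csv` and `cohort.json`.
#' @return data frame of violations (`subject_id`, `replicate`, `channel`,
#'   `problem`); zero rows when the directory is valid.
#' @export
validate_data_dir <- function(path) {
  assert_that(dir.exists(path), "path does not exist")
  violations <- data.frame(subject_id = character(0),
                           replicate = integer(0), channel = character(0),
                           problem = character(0), stringsAsFactors = FALSE)
  add <- function(sid, rep, ch, problem) {
    violations <<- rbind(violations, data.frame(
      subject_id = sid, replicate = rep, channel = ch, problem = problem,
      stringsAsFactors = FALSE))
  }
  csv_path <- file.path(path, "waveforms.csv")
  json_path <- file.path(path, "cohort.json")
  if (!file.exists(csv_path)) {
    add(NA, NA, NA, "missing waveforms.csv")
    return(violations)
  }
  if (!file.exists(json_path)) {
    add(NA, NA, NA, "missing cohort.json")
    return(violations)
  }
  long <- tryCatch(utils::read.csv(csv_path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
  if (is.null(long)) {
    add(NA, NA, NA, "unreadable waveforms.csv")
    return(violations)
  }
  meta <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta)) {
    add(NA, NA, NA, "unreadable cohort.json")
    return(violations)
  }
  need_cols <- c("subject_id", "replicate", "channel", "t_seconds", "value")
  missing_cols <- setdiff(need_cols, names(long))
  if (length(missing_cols)) {
    add(NA, NA, NA, paste("missing column(s):",
                          paste(missing_cols, collapse = ", ")))
    return(violations)
  }
  labelled <- meta$subjects$subject_id %||% character(0)
  for (sid in unique(long$subject_id)) {
    if (!(sid %in% labelled)) add(sid, NA, NA, "no label in cohort.json")
    sub <- long[long$subject_id == sid, ]
    for (rep in unique(sub$replicate)) {
      rr <- sub[sub$replicate == rep, ]
      chans <- unique(rr$channel)
      for (ch in setdiff(CHANNELS, chans))
        add(sid, rep, ch, "channel missing")
      lens <- table(rr$channel)
      if (length(unique(as.integer(lens))) > 1)
        add(sid, rep, NA, "unequal channel lengths")
      vals <- suppressWarnings(as.numeric(rr$value))
      bad <- which(!is.finite(vals))
      if (length(bad))
        add(sid, rep, rr$channel[bad[1]],
            sprintf("non-finite value at row %d", bad[1]))
    }
  }
  violations
}
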