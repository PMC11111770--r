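.stage_exit_codes <- c(config = 2, simulate = 10, qc = 11, tiling = 12,
                       features = 13, train = 14, predict = 15,
                       evaluate = 16, io = 17)

.stage_error <- function(stage, message) {
  structure(class = c("cytoscreen_stage_error", "error", "condition"),
            list(message = sprintf("[%s] %s", stage, message),
                 call = NULL, stage = stage,
                 exit_code = unname(.stage_exit_codes[stage])))
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "cytoscreen_stage_error")) stop(e)
    stop(.stage_error(stage, conditionMessage(e)))
  })
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()].
#' Accepts a YAML file path or a list; unset fields take defaults.
#'
#' Schema (YAML keys): `seed`, `out_dir`, `cohort: {n_slides,
#' prevalences}`, `tiling: {patch_size_px, stride_px}`,
#' `features: {n_bins, include_counts}`, `forest: {ntree, mtry, seed}`,
#' `dedup_iou`, `split_fraction`, `stratum`,
#' `qc: {blur, incomplete_scan, low_cellularity}`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 17L, out_dir = "cytoscreen-run",
    cohort = list(n_slides = 200L, prevalences = NULL),
    tiling = list(patch_size_px = 1024L, stride_px = 768L),
    features = list(n_bins = 10L, include_counts = TRUE),
    forest = list(ntree = 500L, mtry = NULL, seed = 20140101L),
    dedup_iou = 0.5, split_fraction = 0.2, stratum = "ALL_ABNORMAL",
    qc = list(blur = 0.5, incomplete_scan = 0.3, low_cellularity = 0.5)
  )
  cfg <- utils::modifyList(defaults, config)
  .run_stage("config", {
    stopifnot(cfg$cohort$n_slides >= 10,
              cfg$split_fraction > 0, cfg$split_fraction < 1)
    match.arg(cfg$stratum, risk_strata())
  })
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the end-to-end screening pipeline
#'
#' Orchestrates simulate -> tiling validation -> features -> train ->
#' predict -> evaluate on a synthetic cohort, writing a deterministic
#' artifact set to `cfg$out_dir`: `features.csv`, `model.rds`,
#' `predictions.csv`, `report.json` and `run.log` (provenance: package
#' version, seeds, config echo). Any stage failure aborts with a
#' stage-named error carrying a stage-specific exit code.
#'
#' @param cfg A [pipeline_config()] (or list/path coercible to one).
#' @return Invisibly, a named list of artifact paths plus the held-out
#'   evaluation summary.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(features = file.path(cfg$out_dir, "features.csv"),
                model = file.path(cfg$out_dir, "model.rds"),
                predictions = file.path(cfg$out_dir, "predictions.csv"),
                report = file.path(cfg$out_dir, "report.json"),
                log = file.path(cfg$out_dir, "run.log"))

  .run_stage("tiling", {
    tile_slide(4096, 4096, cfg$tiling$patch_size_px, cfg$tiling$stride_px)
  })

  cohort <- .run_stage("simulate", {
    prev <- cfg$cohort$prevalences
    if (is.null(prev)) prev <- training_prevalences()
    generate_cohort(cohort_config(cfg$cohort$n_slides, prevalences = prev,
                                  seed = cfg$seed))
  })

  X <- .run_stage("features", {
    bins <- seq(0, 1, length.out = cfg$features$n_bins + 1)
    extract_feature_matrix(cohort$sets, bins = bins,
                           include_counts = isTRUE(cfg$features$include_counts))
  })
  write_feature_matrix(X, paths$features, truth = cohort$truth)

  n <- nrow(X)
  set.seed(cfg$seed)
  test_idx <- sort(sample.int(n, max(1L, round(cfg$split_fraction * n))))
  train_idx <- setdiff(seq_len(n), test_idx)

  model <- .run_stage("train", {
    train_slide_classifier(X[train_idx, , drop = FALSE],
                           cohort$truth[train_idx],
                           ntree = cfg$forest$ntree, mtry = cfg$forest$mtry,
                           seed = cfg$forest$seed)
  })
  write_slide_classifier(model, paths$model)

  pred <- .run_stage("predict", {
    predict_slide_grade(model, X[test_idx, , drop = FALSE])
  })
  pred_df <- data.frame(slide_id = rownames(X)[test_idx],
                        true_grade = cohort$truth[test_idx],
                        predicted_grade = pred$grade,
                        abnormality = pred$abnormality)
  write.csv(pred_df, paths$predictions, row.names = FALSE, quote = FALSE)

  report <- .run_stage("evaluate", {
    ct <- confusion_for_stratum(pred_df$predicted_grade, pred_df$true_grade,
                                cfg$stratum)
    rep <- diagnostic_metrics(ct)
    truth_bin <- stratum_membership(pred_df$true_grade, cfg$stratum)
    score <- if (cfg$stratum == "ALL_ABNORMAL") pred$abnormality
             else stratum_score(pred$prob, cfg$stratum)
    rep$auc <- if (any(truth_bin) && !all(truth_bin)) {
      roc_auc(score, truth_bin, seed = cfg$seed)[c("auc", "lower", "upper")]
    } else NULL
    rep
  })
  write_diagnostic_report(report, paths$report)

  writeLines(c(
    sprintf("cytoscreen %s | R %s", as.character(packageVersion("cytoscreen")),
            getRversion()),
    sprintf("seed: %d | forest seed: %d", cfg$seed, cfg$forest$seed),
    sprintf("config: %s",
            jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")),
    sprintf("slides: %d (train %d / test %d)", n, length(train_idx),
            length(test_idx)),
    sprintf("oob_accuracy: %.4f", model$oob_accuracy)
  ), paths$log)

  invisible(c(paths, list(report_object = report, model = model,
                          oob_accuracy = model$oob_accuracy)))
}
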