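# End-to-end driver: simulate -> train Rt and CCS models -> calibrate
# tolerance windows -> build the predicted database -> annotate features
# under both identification strategies.

#' Default pipeline configuration
#'
#' All stochastic stages derive their seeds from the single \code{seed};
#' rerunning with an identical configuration reproduces identical outputs.
#'
#' @param seed Master seed.
#' @param n_library Standards library size.
#' @param split Fraction of Rt compounds used for training (rest held
#'   out).
#' @param folds Cross-validation folds for the Rt model.
#' @param n_clusters CCS cluster count or \code{"auto"}.
#' @param run_length Chromatographic run length (min).
#' @param mz_tol m/z match tolerance (Th).
#' @param n_true,n_decoy,n_noise Simulated feature counts.
#' @param rt_noise,ccs_noise Generator measurement-noise SDs.
#' @return Named configuration list.
#' @export
pipeline_config <- function(seed = 1L, n_library = 200L, split = 0.8,
                            folds = 10L, n_clusters = "auto",
                            run_length = 17, mz_tol = 0.005,
                            n_true = 40L, n_decoy = 30L, n_noise = 10L,
                            rt_noise = 0.3, ccs_noise = 2) {
  list(seed = as.integer(seed), n_library = as.integer(n_library),
       split = split, folds = as.integer(folds), n_clusters = n_clusters,
       run_length = run_length, mz_tol = mz_tol,
       n_true = as.integer(n_true), n_decoy = as.integer(n_decoy),
       n_noise = as.integer(n_noise), rt_noise = rt_noise,
       ccs_noise = ccs_noise)
}

#' Recovery statistics against planted truth labels
#'
#' Fraction of planted true (feature, metabolite, adduct) pairs retained by
#' a report, and fraction of planted decoy hits removed between two
#' reports.
#'
#' @param report_1,report_2 \code{annotation_report}s under the weak and
#'   strict strategy.
#' @param labels Truth labels from \code{\link{simulate_feature_table}}.
#' @return List: \code{true_pair_retention_pct} (strict strategy),
#'   \code{decoy_removal_pct}, \code{n_true_pairs}, \code{n_decoy_hits_1},
#'   \code{n_decoy_hits_2}.
#' @export
evaluate_recovery <- function(report_1, report_2, labels) {
  pair_key <- function(df) paste(df$feature_id, df$metabolite_id, df$adduct)
  truth_true <- labels[labels$kind == "true", , drop = FALSE]
  truth_decoy <- labels[labels$kind == "decoy", , drop = FALSE]
  retained <- mean(pair_key(truth_true) %in% pair_key(report_2$hits))
  decoy_ids <- unique(truth_decoy$metabolite_id)
  n_d1 <- sum(report_1$hits$metabolite_id %in% decoy_ids)
  n_d2 <- sum(report_2$hits$metabolite_id %in% decoy_ids)
  list(
    true_pair_retention_pct = 100 * retained,
    decoy_removal_pct = if (n_d1 > 0) 100 * (n_d1 - n_d2) / n_d1 else NA_real_,
    n_true_pairs = nrow(truth_true),
    n_decoy_hits_1 = n_d1,
    n_decoy_hits_2 = n_d2
  )
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: library generation, measurement simulation, QSRR Rt
#' training (seeded train/held-out split, k-fold CV on the training
#' portion), cluster-based CCS training, calibration of both tolerance
#' windows, predicted-database assembly over the candidate pool with
#' measured standards merged in, feature simulation with planted decoys,
#' and annotation under the m/z-only and m/z + CCS + Rt strategies. Counts
#' at every filtering step are collected in \code{$log}.
#'
#' @param config Configuration from \code{\link{pipeline_config}}.
#' @param out Optional output directory; when given, the database CSV,
#'   calibration JSON, annotation reports and the configuration itself are
#'   written there.
#' @return List of artifacts: library, measurements, rt_model, rt_cv,
#'   rt_holdout, ccs_model, ccs_calibration, tolerances, db, features,
#'   report_mz, report_full, stats, recovery, log.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL) {
  seed <- config$seed
  log <- list()

  lib <- generate_library(config$n_library, seed = seed)
  meas <- simulate_measurements(lib, seed = seed + 1L,
                                rt_noise = config$rt_noise,
                                ccs_noise = config$ccs_noise)
  log$n_library <- nrow(lib$records)
  log$n_ccs_entries <- nrow(meas$ccs_entries)

  # ---- Rt model -----------------------------------------------------------
  std <- meas$standards
  rt_desc <- lib$descriptors
  rt_desc[std$descriptor_incomplete, ] <- NA_real_  # exclusion path
  ts <- build_rt_training_set(std, descriptors = rt_desc)
  log$n_rt_excluded_incomplete <- length(ts$excluded)
  n_rt <- length(ts$rt)
  set.seed(seed + 2L)
  train_idx <- sort(sample.int(n_rt, round(config$split * n_rt)))
  rt_model <- fit_rt_model(ts$descriptors[train_idx, , drop = FALSE],
                           ts$rt[train_idx], run_length = config$run_length,
                           seed = seed + 3L)
  rt_cv <- cross_validate_rt(ts$descriptors[train_idx, , drop = FALSE],
                             ts$rt[train_idx], folds = config$folds,
                             seed = seed + 4L)
  rt_model$cv_metrics <- rt_cv[c("mean_r2", "mean_mae", "sd_mae")]
  holdout_idx <- setdiff(seq_len(n_rt), train_idx)
  rt_holdout <- NULL
  if (length(holdout_idx) >= 3L) {
    pred <- predict_rt(rt_model,
                       descriptors = ts$descriptors[holdout_idx, , drop = FALSE])
    rt_holdout <- calibrate_property(pred$rt_pred, ts$rt[holdout_idx], "rt")
  }
  rt_tol <- rt_tolerance_from_cv(rt_cv)
  log$n_rt_train <- length(train_idx)
  log$n_rt_holdout <- length(holdout_idx)

  # ---- CCS model ----------------------------------------------------------
  ccs <- meas$ccs_entries
  ccs_desc <- lib$descriptors[match(ccs$id, lib$records$id), , drop = FALSE]
  n_ccs <- nrow(ccs)
  set.seed(seed + 5L)
  ccs_train <- sort(sample.int(n_ccs, round(config$split * n_ccs)))
  ccs_test <- setdiff(seq_len(n_ccs), ccs_train)
  ccs_model <- fit_ccs_model(ccs_desc[ccs_train, , drop = FALSE],
                             ccs$mz[ccs_train], ccs$adduct[ccs_train],
                             ccs$ccs_A2[ccs_train],
                             n_clusters = config$n_clusters,
                             seed = seed + 6L)
  ccs_pred <- predict_ccs_features(ccs_model,
                                   ccs_desc[ccs_test, , drop = FALSE],
                                   ccs$mz[ccs_test], ccs$adduct[ccs_test])
  ok <- ccs_pred$ok
  ccs_calibration <- calibrate_property(ccs_pred$ccs_pred[ok],
                                        ccs$ccs_A2[ccs_test][ok], "ccs")
  log$n_ccs_train <- length(ccs_train)
  log$n_ccs_validation <- sum(ok)

  # ---- database -----------------------------------------------------------
  pool <- metabolite_pool()
  extra <- pool[!pool$smiles %in% lib$records$smiles, , drop = FALSE]
  candidates <- rbind(
    lib$records[, c("id", "name", "formula", "smiles")],
    if (nrow(extra) > 0L) data.frame(
      id = sprintf("POOL%04d", seq_len(nrow(extra))), name = extra$name,
      formula = NA_character_, smiles = extra$smiles,
      stringsAsFactors = FALSE) else NULL)
  built <- build_database(candidates, ccs_model, rt_model)
  log$n_db_rejects <- nrow(built$rejects)
  measured_tbl <- data.frame(
    metabolite_id = ccs$id, adduct = ccs$adduct, mz = ccs$mz,
    ccs_A2 = ccs$ccs_A2,
    rt_min = std$rt_min[match(ccs$id, std$id)],
    polarity = ccs$polarity, stringsAsFactors = FALSE)
  db <- merge_measured(built$entries, measured_tbl)
  log$n_db_rows <- nrow(db)
  log$n_db_measured <- sum(db$source == "measured")
  log$n_rt_clipped <- sum(built$entries$rt_flag, na.rm = TRUE)

  # ---- features and annotation -------------------------------------------
  sim <- simulate_feature_table(db, config$n_true, config$n_decoy,
                                config$n_noise, seed = seed + 7L,
                                mz_tol = config$mz_tol,
                                ccs_tol = ccs_calibration$tolerance,
                                rt_tol = rt_tol)
  strat_mz <- match_strategy(mz_tol = config$mz_tol)
  strat_full <- match_strategy(mz_tol = config$mz_tol,
                               use_ccs = TRUE,
                               ccs_tol = ccs_calibration$tolerance,
                               use_rt = TRUE, rt_tol = rt_tol)
  report_mz <- annotate_table(sim$features, sim$db, strat_mz)
  report_full <- annotate_table(sim$features, sim$db, strat_full)
  stats <- hit_statistics(report_mz, report_full)
  recovery <- evaluate_recovery(report_mz, report_full, sim$labels)

  result <- list(config = config, library = lib, measurements = meas,
                 rt_model = rt_model, rt_cv = rt_cv, rt_holdout = rt_holdout,
                 rt_tolerance = rt_tol, ccs_model = ccs_model,
                 ccs_calibration = ccs_calibration, db = db,
                 db_rejects = built$rejects, features = sim$features,
                 feature_labels = sim$labels, feature_db = sim$db,
                 report_mz = report_mz, report_full = report_full,
                 stats = stats, recovery = recovery, log = log)

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_database(db, file.path(out, "database.csv"))
    jsonlite::write_json(list(
      ccs = unclass(ccs_calibration),
      rt_cv = rt_cv[c("mean_r2", "mean_mae", "sd_mae")],
      rt_tolerance_min = rt_tol,
      rt_holdout = if (!is.null(rt_holdout)) unclass(rt_holdout) else NULL
    ), file.path(out, "calibration.json"), auto_unbox = TRUE, digits = NA)
    write_annotation_report(report_mz, file.path(out, "strategy_mz"))
    write_annotation_report(report_full, file.path(out, "strategy_full"))
    jsonlite::write_json(c(config, list(log = log)),
                         file.path(out, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(sim$features, file.path(out, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$labels, file.path(out, "feature_labels.csv"),
                     row.names = FALSE)
  }
  result
}
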