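# End-to-end orchestration -----------------------------------------------------

#' Run the full two-stage pipeline on a cohort
#'
#' Stage 1 (LOSO heel-strike detection, filling `hs_pred`), stage 2 (LOSO
#' VO2 estimation for the requested models under both heel-strike sources),
#' GT-vs-Pred paired comparisons per model, and TreeSHAP attributions for a
#' random-forest regressor fit on the full GT window table.
#'
#' @param cohort a `cohort`.
#' @param config a [run_config()]; its `seed` drives every stochastic stage.
#' @param models stage-2 models to evaluate (subset of `"rf"`, `"stacked"`,
#'   `"xgb"`, `"elm"`).
#' @param include_demographics use the 20-dim stage-2 feature vector.
#' @param explain_windows number of windows to explain with TreeSHAP
#'   (0 disables the explanation step).
#' @return A `pipeline_result` with `hs` (stage-1 report), `vo2` (named list
#'   `model.source` of `loso_report`s), `comparisons` (per model),
#'   `shap` (attributions + ranking, or `NULL`) and `config`.
#' @export
run_pipeline <- function(cohort, config = run_config(),
                         models = c("rf", "stacked"),
                         include_demographics = FALSE,
                         explain_windows = 100) {
  hs <- run_hs_loso(cohort, config)
  cohort <- hs$cohort
  tabs <- list(gt = cohort_window_tables(cohort, "gt", include_demographics, config),
               pred = cohort_window_tables(cohort, "pred", include_demographics, config))
  vo2 <- list()
  comparisons <- list()
  for (m in models) {
    rg <- run_vo2_loso(cohort, "gt", include_demographics, m, config, tabs$gt)
    rp <- run_vo2_loso(cohort, "pred", include_demographics, m, config, tabs$pred)
    vo2[[paste0(m, ".gt")]] <- rg
    vo2[[paste0(m, ".pred")]] <- rp
    comparisons[[m]] <- compare_gt_pred(rg, rp)
  }
  shap <- NULL
  if (explain_windows > 0) {
    full <- do.call(rbind, tabs$gt)
    fcols <- stage2_feature_names(include_demographics)
    rf <- fit_rf_regressor(as.matrix(full[, fcols]), full$target_vo2_norm,
                           trees = config$stage2$rf_trees,
                           max_depth = config$stage2$rf_depth,
                           min_leaf = config$stage2$rf_min_leaf,
                           seed = derive_seed(config$seed, "explain-rf"))
    xe <- as.matrix(full[seq_len(min(explain_windows, nrow(full))), fcols])
    att <- shap_attributions(rf, xe)
    shap <- list(attributions = att, ranking = importance_ranking(att))
  }
  structure(list(hs = hs, vo2 = vo2, comparisons = comparisons, shap = shap,
                 config = config),
            class = "pipeline_result")
}

#' Write pipeline reports as CSV files
#'
#' Emits `hs_report.csv` (per-fold stage-1 metrics), `vo2_report.csv`
#' (per-fold R-squared with inclusion flags across conditions),
#' `comparison.csv` (GT vs Pred per model with paired statistics),
#' `shap_ranking.csv` when present, and `manifest.yaml` capturing the
#' configuration, seed and fold membership. Numeric cells use fixed
#' formatting so identical runs serialize identically.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixed_csv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- sprintf("%.6f", df[[j]])
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(names(df), collapse = ","),
                 do.call(paste, c(df, sep = ","))), con)
  }
  fixed_csv(result$hs$folds, file.path(dir, "hs_report.csv"))
  vo2 <- do.call(rbind, lapply(names(result$vo2), function(nm) {
    r <- result$vo2[[nm]]
    cbind(condition = nm, model = r$model, hs_source = r$hs_source,
          r$folds)
  }))
  vo2$exclusion_reason[is.na(vo2$exclusion_reason)] <- ""
  fixed_csv(vo2, file.path(dir, "vo2_report.csv"))
  comp <- do.call(rbind, lapply(names(result$comparisons), function(m) {
    cc <- result$comparisons[[m]]
    data.frame(model = m, median_gt = cc$median_gt, median_pred = cc$median_pred,
               delta_pred_minus_gt = cc$delta_median, t_p = cc$stats$t_p,
               wilcoxon_p = cc$stats$wilcoxon_p, cohens_d = cc$stats$cohens_d,
               shapiro_p = cc$stats$shapiro_p)
  }))
  fixed_csv(comp, file.path(dir, "comparison.csv"))
  if (!is.null(result$shap))
    fixed_csv(result$shap$ranking, file.path(dir, "shap_ranking.csv"))
  manifest <- list(seed = result$config$seed,
                   window_s = result$config$window_s,
                   stage1 = result$config$stage1,
                   stage2 = result$config$stage2,
                   loso = result$config$loso,
                   folds = result$hs$train_ids)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Default desk-scale study cohort
#'
#' The synthetic analogue of the modeled study at a size that runs in
#' minutes: `n_subjects` subjects walking the five-stage graded protocol with
#' `stage_duration_s`-second stages (all other simulator parameters at their
#' defaults), generated from one master seed.
#'
#' @param n_subjects cohort size.
#' @param stage_duration_s seconds per protocol stage.
#' @param seed master seed.
#' @return A `cohort`.
#' @export
default_study_cohort <- function(n_subjects = 12, stage_duration_s = 60,
                                 seed = 1L) {
  cfg <- sim_config(stages = graded_walk_protocol(stage_duration_s), seed = seed)
  generate_cohort(n_subjects, cfg)
}
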