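# LOSO orchestration for both stages ------------------------------------------

# Stratified stage-1 training subsample: every positive sample plus a seeded
# negative subsample, capped at `cap` rows. Keeps per-fold forest training at
# desk scale; class weights are computed on the subsample actually used.
stage1_training_rows <- function(features_by_subject, train_ids, cap, seed) {
  xs <- list()
  ys <- list()
  ids <- list()
  for (s in train_ids) {
    f <- features_by_subject[[s]]
    pos <- which(f$labels == 1L)
    xs[[s]] <- f$values[pos, , drop = FALSE]
    ys[[s]] <- f$labels[pos]
    ids[[s]] <- rep(s, length(pos))
  }
  n_pos <- sum(vapply(ys, length, integer(1)))
  n_neg_total <- max(n_pos, cap - n_pos)
  per_subj <- ceiling(n_neg_total / length(train_ids))
  for (s in train_ids) {
    f <- features_by_subject[[s]]
    neg <- which(f$labels == 0L)
    take <- withr::with_seed(derive_seed(seed, "neg-sub", match(s, train_ids)),
                             sort(sample(neg, min(length(neg), per_subj))))
    xs[[paste0(s, ".n")]] <- f$values[take, , drop = FALSE]
    ys[[paste0(s, ".n")]] <- f$labels[take]
    ids[[paste0(s, ".n")]] <- rep(s, length(take))
  }
  list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
       subject = unlist(ids, use.names = FALSE))
}

#' Run stage-1 heel-strike detection under LOSO
#'
#' For each fold the stacked classifier is fit on the training subjects
#' (its base RF and ELM double as the standalone RF and ELM models, and
#' the ELM+RF ensemble averages their probabilities), every model is applied
#' to the held-out subject's full sample stream, detections are consolidated
#' into events, and both sample-level F1 and event-level F1 (+/- 3-sample
#' matching) are recorded. The held-out subject's `hs_pred` is filled from
#' the configured prediction model so stage 2 can run on predicted events
#' without subject-level leakage.
#'
#' @param cohort a `cohort`.
#' @param config a [run_config()].
#' @param event_tolerance event-matching tolerance in samples.
#' @return List: `folds` (data.frame with one row per subject x model:
#'   `held_out_subject`, `model`, `f1_sample`, `f1_event`, `n_events_true`,
#'   `n_events_pred`), `aggregates` (per model, from event F1), `cohort`
#'   (with `hs_pred` filled), `train_ids` (per-fold training subjects, for
#'   leakage audit).
#' @export
run_hs_loso <- function(cohort, config = run_config(), event_tolerance = 3) {
  ids <- subject_ids(cohort)
  s1 <- config$stage1
  feats <- lapply(cohort$subjects, build_sample_features, w = config$sample_window_w)
  names(feats) <- ids
  folds <- loso_folds(ids)
  rows <- list()
  train_log <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr <- stage1_training_rows(feats, fold$train, s1$train_cap,
                               derive_seed(config$seed, "s1fold", fi))
    stopifnot(!fold$test %in% tr$subject)      # leakage audit
    train_log[[fold$test]] <- fold$train
    stacked <- fit_stacked_hs(tr$x, tr$y, tr$subject, config,
                              seed = derive_seed(config$seed, "s1fit", fi))
    test_x <- feats[[fold$test]]$values
    truth <- feats[[fold$test]]$labels
    true_idx <- which(truth == 1L)
    p <- list(rf = predict_rf_proba(stacked$base_rf, test_x),
              elm = predict_elm_proba(stacked$base_elm, test_x))
    p$ensemble <- (p$rf + p$elm) / 2
    p$stacked <- {
      z <- cbind(p_rf = p$rf, p_elm = p$elm)
      predict(stacked$meta, xgboost::xgb.DMatrix(z))
    }
    for (m in names(p)) {
      lab <- classify_hs(p[[m]], s1$tau)
      ev <- consolidate_events(lab, s1$min_gap_samples, p[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        held_out_subject = fold$test, model = m,
        f1_sample = f1_hs(truth, lab, 0),
        f1_event = event_f1(true_idx, ev$event_indices, event_tolerance),
        n_events_true = length(true_idx),
        n_events_pred = length(ev$event_indices))
      if (m == s1$pred_model) {
        si <- match(fold$test, ids)
        cohort$subjects[[si]]$hs_pred <- events_to_labels(ev, nrow(test_x))
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  aggregates <- lapply(split(folds_df, folds_df$model), function(d)
    aggregate_folds(d$f1_event))
  list(folds = folds_df, aggregates = aggregates, cohort = cohort,
       train_ids = train_log)
}

#' Build window feature tables for a whole cohort
#'
#' @param cohort a `cohort`.
#' @param hs_source `"gt"` or `"pred"`.
#' @param include_demographics append demographic features.
#' @param config a [run_config()].
#' @return Named list of per-subject window tables (see
#'   [build_window_table()]).
#' @export
cohort_window_tables <- function(cohort, hs_source = "gt",
                                 include_demographics = FALSE,
                                 config = run_config()) {
  out <- lapply(cohort$subjects, build_window_table, hs_source = hs_source,
                include_demographics = include_demographics,
                window_s = config$window_s)
  names(out) <- subject_ids(cohort)
  out
}

#' Run stage-2 VO2 estimation under LOSO
#'
#' Fits the requested regressor on all training subjects' windows for each
#' fold, predicts the held-out subject's windows, scores R-squared, applies
#' the fold-exclusion rule (target variance below threshold or too few test
#' windows), and aggregates over included folds.
#'
#' @param cohort a `cohort` (with `hs_pred` filled when
#'   `hs_source = "pred"`).
#' @param hs_source `"gt"` or `"pred"` heel-strike feature source.
#' @param include_demographics use the 20-dim feature vector.
#' @param model `"rf"`, `"stacked"`, `"xgb"` or `"elm"`.
#' @param config a [run_config()].
#' @param tables optional precomputed [cohort_window_tables()] result.
#' @return A `loso_report`: `folds` data.frame (`held_out_subject`, `task`,
#'   `metric_name`, `metric_value`, `n_test_windows`, `target_variance`,
#'   `included`, `exclusion_reason`), `aggregates`, plus the run metadata.
#' @export
run_vo2_loso <- function(cohort, hs_source = "gt", include_demographics = FALSE,
                         model = "rf", config = run_config(), tables = NULL) {
  if (is.null(tables))
    tables <- cohort_window_tables(cohort, hs_source, include_demographics, config)
  ids <- names(tables)
  fcols <- stage2_feature_names(include_demographics)
  folds <- loso_folds(ids)
  rows <- lapply(seq_along(folds), function(fi) {
    fold <- folds[[fi]]
    tr <- do.call(rbind, tables[fold$train])
    te <- tables[[fold$test]]
    stopifnot(!fold$test %in% tr$subject_id)   # leakage audit
    fit <- fit_vo2_model(model, as.matrix(tr[, fcols]), tr$target_vo2_norm,
                         tr$subject_id, config,
                         seed = derive_seed(config$seed, paste0("vo2-", model), fi))
    pred <- predict_vo2(fit, as.matrix(te[, fcols]))
    y <- te$target_vo2_norm
    data.frame(held_out_subject = fold$test, task = "VO2",
               metric_name = "r_squared",
               metric_value = if (length(y) >= 2) r_squared(y, pred) else NA_real_,
               n_test_windows = length(y),
               target_variance = if (length(y) >= 2) var(y) else 0)
  })
  folds_df <- filter_folds(do.call(rbind, rows), config$loso$var_threshold,
                           config$loso$min_windows)
  structure(list(folds = folds_df,
                 aggregates = aggregate_folds(folds_df$metric_value,
                                              folds_df$included),
                 model = model, hs_source = toupper(hs_source),
                 include_demographics = include_demographics, config = config),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<LOSO VO2 report: %s, %s-HS%s>\n", x$model, x$hs_source,
              if (x$include_demographics) " + demographics" else ""))
  cat(sprintf("  median R2 = %.3f, mean = %.3f (sd %.3f), best = %.3f, worst = %.3f over %d/%d folds\n",
              a$median, a$mean, a$std, a$best, a$worst, a$n_folds, nrow(x$folds)))
  excl <- x$folds[!x$folds$included, ]
  if (nrow(excl) > 0)
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%s)", excl$held_out_subject,
                              excl$exclusion_reason), collapse = ", ")))
  invisible(x)
}
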