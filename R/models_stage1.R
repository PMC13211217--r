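# stage1_models: heel-strike classifiers --------------------------------------
#
# Four classifiers over the 15-dim per-sample features:
#   * RF:        150-tree bagged forest, m = sqrt(d) features per split,
#                balanced class weights w_c = N / (2 N_c), OOB error exposed.
#   * ELM:       closed-form network (labels coded -1/+1, sigmoid probability).
#   * ELM+RF:    unweighted mean of the two class-1 probabilities.
#   * Stacked:   XGBoost meta-learner on the 2-dim meta-feature
#                z = [p_RF, p_ELM], built from subject-grouped out-of-fold
#                base predictions; decision p_meta >= tau.

#' Balanced class weights
#'
#' `w_c = N / (2 N_c)` for each class, so a balanced sample gets weights 1.
#'
#' @param labels binary 0/1 vector.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
balanced_class_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n0 == 0 || n1 == 0) abort("both classes must be present")
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Fit the heel-strike random forest
#'
#' Probability forest of `trees` bagged decision trees with `floor(sqrt(d))`
#' candidate features per split and balanced class weights; the out-of-bag
#' (OOB) error of the fit is stored as `oob_error`.
#'
#' @param x n x d sample-feature matrix.
#' @param labels binary 0/1 heel-strike labels (both classes present).
#' @param trees number of trees.
#' @param seed integer seed.
#' @return An `hs_rf` model wrapping a `ranger` probability forest.
#' @export
fit_rf_hs <- function(x, labels, trees = 150, seed = 1L) {
  w <- balanced_class_weights(labels)
  y <- factor(labels, levels = c(0, 1))
  rf <- ranger::ranger(x = as.matrix(x), y = y, num.trees = trees,
                       mtry = max(1L, floor(sqrt(ncol(x)))),
                       probability = TRUE, class.weights = unname(w),
                       num.threads = 1, seed = seed)
  structure(list(model = rf, class_weights = w, oob_error = rf$prediction.error),
            class = "hs_rf")
}

#' Class-1 probability from the heel-strike forest
#' @param model an `hs_rf`.
#' @param x feature matrix.
#' @return Numeric probabilities (fraction of trees voting heel strike).
#' @export
predict_rf_proba <- function(model, x) {
  p <- predict(model$model, data = as.matrix(x), num.threads = 1)$predictions
  unname(p[, "1"])
}

#' Fit the heel-strike ELM
#'
#' Trains [fit_elm()] on labels coded -1/+1 so that the sigmoid probability
#' `sigma(h'beta)` crosses 0.5 exactly at the least-squares decision boundary.
#'
#' @inheritParams fit_rf_hs
#' @param n_hidden hidden units.
#' @param alpha ridge penalty (0 = pseudo-inverse).
#' @return An `elm_model`.
#' @export
fit_elm_hs <- function(x, labels, n_hidden = 150, alpha = 0, seed = 1L) {
  fit_elm(x, ifelse(labels == 1, 1, -1), n_hidden = n_hidden,
          alpha = alpha, seed = seed)
}

#' ELM+RF ensemble probability
#'
#' Unweighted mean of the RF and ELM class-1 probabilities (symmetric in the
#' two arguments).
#'
#' @param rf an `hs_rf`.
#' @param elm an `elm_model` fit on the same feature space.
#' @param x feature matrix.
#' @return Numeric probabilities.
#' @export
predict_ensemble_elm_rf <- function(rf, elm, x) {
  (predict_rf_proba(rf, x) + predict_elm_proba(elm, x)) / 2
}

# subject-grouped K-fold assignment (balanced, deterministic given seed)
group_kfold <- function(subject_id, k, seed) {
  ids <- unique(subject_id)
  k <- min(k, length(ids))
  ord <- withr::with_seed(seed, sample(ids))
  fold_of <- setNames(rep(seq_len(k), length.out = length(ord)), ord)
  list(k = k, fold = unname(fold_of[subject_id]))
}

#' Fit the stacked heel-strike classifier
#'
#' Base RF and ELM are fit on the full training data for test-time use; the
#' meta-features used to train the XGBoost meta-learner are out-of-fold base
#' predictions from a subject-grouped internal K-fold (K = 5 or the number of
#' training subjects if smaller), so the meta-learner never sees in-sample
#' base predictions.
#'
#' @param x n x d feature matrix.
#' @param labels binary 0/1 labels.
#' @param subject_id per-row subject ids (>= 2 distinct).
#' @param config a [run_config()] (stage-1 hyperparameters are read from it).
#' @param seed integer seed.
#' @return An `hs_stacked` model with fields `base_rf`, `base_elm`, `meta`
#'   (xgboost booster) and `tau`.
#' @export
fit_stacked_hs <- function(x, labels, subject_id, config = run_config(), seed = 1L) {
  if (length(unique(subject_id)) < 2) abort("stacking requires >= 2 training subjects")
  s1 <- config$stage1
  x <- as.matrix(x)
  kf <- group_kfold(subject_id, s1$inner_k, derive_seed(seed, "stack-folds"))
  z <- matrix(NA_real_, nrow(x), 2, dimnames = list(NULL, c("p_rf", "p_elm")))
  for (f in seq_len(kf$k)) {
    tr <- kf$fold != f
    te <- !tr
    rf_f <- fit_rf_hs(x[tr, , drop = FALSE], labels[tr], trees = s1$rf_trees,
                      seed = derive_seed(seed, "stack-rf", f))
    elm_f <- fit_elm_hs(x[tr, , drop = FALSE], labels[tr], n_hidden = s1$elm_hidden,
                        alpha = s1$elm_alpha, seed = derive_seed(seed, "stack-elm", f))
    z[te, 1] <- predict_rf_proba(rf_f, x[te, , drop = FALSE])
    z[te, 2] <- predict_elm_proba(elm_f, x[te, , drop = FALSE])
  }
  meta <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = s1$meta_depth,
                  eta = s1$meta_eta, nthread = 1, subsample = 1,
                  colsample_bytree = 1),
    data = xgboost::xgb.DMatrix(z, label = labels),
    nrounds = s1$meta_nrounds, verbose = 0)
  base_rf <- fit_rf_hs(x, labels, trees = s1$rf_trees, seed = derive_seed(seed, "rf"))
  base_elm <- fit_elm_hs(x, labels, n_hidden = s1$elm_hidden, alpha = s1$elm_alpha,
                         seed = derive_seed(seed, "elm"))
  structure(list(base_rf = base_rf, base_elm = base_elm, meta = meta,
                 tau = s1$tau),
            class = "hs_stacked")
}

#' Stacked heel-strike probability
#' @param model an `hs_stacked`.
#' @param x feature matrix.
#' @return Meta-learner probabilities.
#' @export
predict_stacked_hs <- function(model, x) {
  z <- cbind(p_rf = predict_rf_proba(model$base_rf, x),
             p_elm = predict_elm_proba(model$base_elm, x))
  predict(model$meta, xgboost::xgb.DMatrix(z))
}

#' Threshold probabilities into heel-strike labels
#'
#' Label 1 iff `p >= tau` (the boundary value itself is a detection).
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param tau decision threshold in (0, 1).
#' @return Integer 0/1 labels.
#' @export
classify_hs <- function(probabilities, tau = 0.5) {
  as.integer(probabilities >= tau)
}

#' Consolidate per-sample detections into heel-strike events
#'
#' Each maximal run of positive samples collapses to its central sample; then
#' events closer than `min_gap_samples` merge, keeping the higher-probability
#' event when probabilities are supplied, else the earlier one.
#'
#' @param labels binary 0/1 vector.
#' @param min_gap_samples refractory gap (samples).
#' @param probabilities optional per-sample probabilities for tie-breaking.
#' @return An `hs_events` list: `event_indices` (strictly increasing sample
#'   indices, pairwise gaps >= `min_gap_samples`) and `min_gap_samples`.
#' @export
consolidate_events <- function(labels, min_gap_samples = 30, probabilities = NULL) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values == 1)
  ev <- as.integer(floor((starts[pos] + ends[pos]) / 2))
  score <- if (is.null(probabilities)) -ev else probabilities[ev]
  # iteratively merge pairs closer than the refractory gap
  while (length(ev) > 1 && any(diff(ev) < min_gap_samples)) {
    i <- which(diff(ev) < min_gap_samples)[1]
    drop <- if (score[i] >= score[i + 1]) i + 1L else i
    ev <- ev[-drop]
    score <- score[-drop]
  }
  structure(list(event_indices = ev, min_gap_samples = min_gap_samples),
            class = "hs_events")
}

#' Events as a binary per-sample signal
#'
#' @param events an `hs_events`.
#' @param n recording length in samples.
#' @return Integer 0/1 vector with one positive sample per event.
#' @export
events_to_labels <- function(events, n) {
  out <- integer(n)
  out[events$event_indices] <- 1L
  out
}
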