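# stage2_models: VO2 regression ------------------------------------------------
#
# Two model families on the window feature table:
#   * RF regressor: 700 bagged trees, depth 18, min leaf 2, d/3 features per
#     split; prediction is the mean over trees.
#   * Stacked regressor: base RF (300 trees, depth 6), base XGBoost
#     (300 rounds, depth 4, eta 0.05, squared-error objective), base ELM
#     (250 hidden units, alpha 0.2); their subject-grouped out-of-fold
#     predictions form the 3-dim meta-feature z = [y_RF, y_XGB, y_ELM],
#     standardized with training statistics and combined by a closed-form
#     ridge meta-learner (unpenalized intercept).

#' Fit the VO2 random-forest regressor
#'
#' @param x n x d window-feature matrix.
#' @param y normalized VO2 targets.
#' @param trees,max_depth,min_leaf forest hyperparameters.
#' @param seed integer seed.
#' @return A `vo2_rf` wrapping a `ranger` regression forest; the training
#'   matrix is retained for TreeSHAP cover computation.
#' @export
fit_rf_regressor <- function(x, y, trees = 700, max_depth = 18, min_leaf = 2,
                             seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("need at least 3 training rows")
  rf <- ranger::ranger(x = x, y = y, num.trees = trees,
                       mtry = max(1L, ceiling(ncol(x) / 3)),
                       max.depth = max_depth, min.node.size = min_leaf,
                       num.threads = 1, seed = seed)
  structure(list(model = rf, train_x = x, feature_names = colnames(x)),
            class = "vo2_rf")
}

#' @export
predict.vo2_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$train_x)) abort("feature dimension mismatch")
  unname(predict(object$model, data = newdata, num.threads = 1)$predictions)
}

#' Fit the XGBoost VO2 regressor
#'
#' Squared-error objective with second-order updates; subsample and column
#' sampling left at 1.
#'
#' @inheritParams fit_rf_regressor
#' @param nrounds,max_depth,eta booster hyperparameters.
#' @return A `vo2_xgb` wrapping an xgboost booster (stores `base_score`).
#' @export
fit_xgb_regressor <- function(x, y, nrounds = 300, max_depth = 4, eta = 0.05,
                              seed = 1L) {
  x <- as.matrix(x)
  base_score <- 0.5
  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = max_depth,
                  eta = eta, nthread = 1, subsample = 1, colsample_bytree = 1,
                  base_score = base_score, seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = nrounds, verbose = 0)
  structure(list(model = bst, base_score = base_score,
                 feature_names = colnames(x), d = ncol(x)),
            class = "vo2_xgb")
}

#' @export
predict.vo2_xgb <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) abort("feature dimension mismatch")
  unname(predict(object$model, xgboost::xgb.DMatrix(newdata)))
}

# closed-form ridge with unpenalized intercept on standardized meta-features
ridge_fit <- function(z, y, lambda) {
  zi <- cbind(1, z)
  pen <- diag(c(0, rep(lambda, ncol(z))))
  coef <- solve(crossprod(zi) + pen, crossprod(zi, y))
  drop(coef)
}

#' Fit the stacked VO2 regressor
#'
#' @param x n x d window-feature matrix.
#' @param y normalized VO2 targets.
#' @param subject_id per-row subject ids (>= 2 distinct).
#' @param config a [run_config()] (stage-2 hyperparameters).
#' @param seed integer seed.
#' @return A `vo2_stacked` with the three base models, the meta scaler
#'   (means/sds of the training meta-features), and ridge coefficients.
#' @export
fit_stacked_regressor <- function(x, y, subject_id, config = run_config(),
                                  seed = 1L) {
  if (length(unique(subject_id)) < 2) abort("stacking requires >= 2 training subjects")
  s2 <- config$stage2
  x <- as.matrix(x)
  fit_bases <- function(xtr, ytr, tag) list(
    rf = fit_rf_regressor(xtr, ytr, trees = s2$base_rf_trees,
                          max_depth = s2$base_rf_depth, min_leaf = 2,
                          seed = derive_seed(seed, paste0("srf", tag))),
    xgb = fit_xgb_regressor(xtr, ytr, nrounds = s2$xgb_rounds,
                            max_depth = s2$xgb_depth, eta = s2$xgb_eta,
                            seed = derive_seed(seed, paste0("sxgb", tag))),
    elm = fit_elm(xtr, ytr, n_hidden = s2$elm_hidden, alpha = s2$elm_alpha,
                  seed = derive_seed(seed, paste0("selm", tag))))
  predict_bases <- function(b, xx) cbind(
    y_rf = predict(b$rf, xx), y_xgb = predict(b$xgb, xx),
    y_elm = predict_elm(b$elm, xx))

  z <- matrix(NA_real_, nrow(x), 3,
              dimnames = list(NULL, c("y_rf", "y_xgb", "y_elm")))
  if (isTRUE(s2$oof_meta)) {
    kf <- group_kfold(subject_id, s2$inner_k, derive_seed(seed, "stack2-folds"))
    for (f in seq_len(kf$k)) {
      tr <- kf$fold != f
      b <- fit_bases(x[tr, , drop = FALSE], y[tr], paste0("f", f))
      z[!tr, ] <- predict_bases(b, x[!tr, , drop = FALSE])
    }
  }
  bases <- fit_bases(x, y, "full")
  if (!isTRUE(s2$oof_meta)) z <- predict_bases(bases, x)   # in-sample variant
  mu <- colMeans(z)
  sdev <- apply(z, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  zs <- sweep(sweep(z, 2, mu), 2, sdev, "/")
  coef <- ridge_fit(zs, y, s2$ridge_lambda)
  structure(list(bases = bases, meta_center = mu, meta_scale = sdev,
                 meta_coef = coef, ridge_lambda = s2$ridge_lambda),
            class = "vo2_stacked")
}

#' @export
predict.vo2_stacked <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  z <- cbind(y_rf = predict(object$bases$rf, newdata),
             y_xgb = predict(object$bases$xgb, newdata),
             y_elm = predict_elm(object$bases$elm, newdata))
  zs <- sweep(sweep(z, 2, object$meta_center), 2, object$meta_scale, "/")
  unname(drop(cbind(1, zs) %*% object$meta_coef))
}

#' Fit a stage-2 model by name
#'
#' @param model one of `"rf"`, `"stacked"`, `"xgb"`, `"elm"`.
#' @inheritParams fit_stacked_regressor
#' @return The fitted model object.
#' @export
fit_vo2_model <- function(model, x, y, subject_id, config = run_config(),
                          seed = 1L) {
  s2 <- config$stage2
  switch(model,
    rf = fit_rf_regressor(x, y, trees = s2$rf_trees, max_depth = s2$rf_depth,
                          min_leaf = s2$rf_min_leaf,
                          seed = derive_seed(seed, "vo2rf")),
    stacked = fit_stacked_regressor(x, y, subject_id, config, seed),
    xgb = fit_xgb_regressor(x, y, nrounds = s2$xgb_rounds,
                            max_depth = s2$xgb_depth, eta = s2$xgb_eta,
                            seed = derive_seed(seed, "vo2xgb")),
    elm = fit_elm(x, y, n_hidden = s2$elm_hidden, alpha = s2$elm_alpha,
                  seed = derive_seed(seed, "vo2elm")),
    abort("unknown stage-2 model '%s'", model))
}

#' Predict from any stage-2 model
#' @param model object from [fit_vo2_model()].
#' @param x feature matrix.
#' @return Numeric predictions on the normalized VO2 scale.
#' @export
predict_vo2 <- function(model, x) {
  if (inherits(model, "elm_model")) predict_elm(model, x) else predict(model, x)
}
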