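# explainability: exact TreeSHAP attributions for the VO2 tree models ---------
#
# The attribution of feature j to a window's prediction is its Shapley value
# under the path-dependent formulation: conditional expectations follow the
# tree's own training-data cover counts, so no external background dataset is
# needed. Local accuracy holds by construction:
# base_value + sum_j phi_j = prediction, per row.

# --- converters to the unified tree-array representation ---------------------

shap_tree <- function(left, right, feature, threshold, value, cover, strict_less) {
  list(left = as.integer(left), right = as.integer(right),
       feature = as.integer(feature), threshold = as.numeric(threshold),
       value = as.numeric(value), cover = as.numeric(cover),
       strict_less = strict_less)
}

# ranger regression forest -> tree arrays; covers computed by routing the
# stored training matrix down each tree (ranger rule: x <= splitval goes left)
ranger_shap_trees <- function(model) {
  stopifnot(inherits(model, "vo2_rf"))
  x <- model$train_x
  lapply(seq_len(model$model$num.trees), function(t) {
    ti <- ranger::treeInfo(model$model, t)
    leaf <- ti$terminal
    left <- ifelse(leaf, -1L, ti$leftChild)
    right <- ifelse(leaf, -1L, ti$rightChild)
    feature <- ifelse(leaf, -1L, ti$splitvarID)
    threshold <- ifelse(leaf, 0, ti$splitval)
    value <- ifelse(leaf, ti$prediction, 0)
    cover <- .tree_cover_cpp(left, right, feature, threshold, x, FALSE)
    shap_tree(left, right, feature, threshold, value, cover, FALSE)
  })
}

# xgboost booster -> tree arrays (xgboost rule: x < split goes Yes/left);
# covers come from the booster's own stored Cover statistics
xgb_shap_trees <- function(model) {
  stopifnot(inherits(model, "vo2_xgb"))
  dt <- xgboost::xgb.model.dt.tree(model = model$model)
  dt <- as.data.frame(dt)
  value_col <- intersect(c("Gain", "Quality"), names(dt))[1]
  lapply(split(dt, dt$Tree), function(td) {
    td <- td[order(td$Node), ]
    id2node <- setNames(td$Node, td$ID)
    leaf <- td$Feature == "Leaf"
    # features may be named (training matrix had colnames) or f<k> indices
    fidx <- if (!is.null(model$feature_names) &&
                any(td$Feature[!leaf] %in% model$feature_names)) {
      match(td$Feature, model$feature_names) - 1L
    } else {
      suppressWarnings(as.integer(sub("^f", "", td$Feature)))
    }
    feature <- ifelse(leaf, -1L, fidx)
    # thresholds are float32 in the booster; recover the exact stored values
    thr <- drop(.float32_round_cpp(matrix(ifelse(leaf, 0, td$Split))))
    shap_tree(left = ifelse(leaf, -1L, unname(id2node[td$Yes])),
              right = ifelse(leaf, -1L, unname(id2node[td$No])),
              feature = feature,
              threshold = thr,
              value = ifelse(leaf, td[[value_col]], 0),
              cover = td$Cover, strict_less = TRUE)
  })
}

#' Exact TreeSHAP attributions
#'
#' Supported models: the random-forest VO2 regressor (`vo2_rf`; per-tree
#' attributions averaged over trees) and the boosted VO2 regressor
#' (`vo2_xgb`; summed over trees plus the base score). ELM and stacked
#' meta-paths have no tree structure and are rejected.
#'
#' @param model a `vo2_rf` or `vo2_xgb`.
#' @param x matrix or data.frame of windows to explain (training feature
#'   order).
#' @return An `attribution_table`: `phi` (n x d matrix of attributions in
#'   normalized-VO2 units), `base_value` (expected model output),
#'   `prediction` (per-row model output), `feature_names`, `data`.
#' @export
shap_attributions <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("no rows to explain")
  if (inherits(model, "vo2_rf")) {
    trees <- ranger_shap_trees(model)
    scale <- 1 / length(trees)
    offset <- 0
    fn <- model$feature_names
  } else if (inherits(model, "vo2_xgb")) {
    trees <- xgb_shap_trees(model)
    scale <- 1
    offset <- model$base_score
    fn <- model$feature_names
    x <- .float32_round_cpp(x)     # xgboost compares in float32 precision
  } else {
    abort("TreeSHAP supports tree ensembles only (vo2_rf, vo2_xgb); got %s",
          paste(class(model), collapse = "/"))
  }
  res <- .treeshap_cpp(trees, x, scale)
  phi <- res$phi
  colnames(phi) <- fn
  structure(list(phi = phi, base_value = res$base_value + offset,
                 prediction = res$base_value + offset + rowSums(phi),
                 feature_names = fn, data = x),
            class = "attribution_table")
}

#' Global importance ranking by mean absolute attribution
#'
#' @param attributions an `attribution_table`.
#' @return data.frame `feature`, `mean_abs_shap` sorted by descending mean
#'   absolute attribution, ties broken alphabetically.
#' @export
importance_ranking <- function(attributions) {
  stopifnot(inherits(attributions, "attribution_table"))
  m <- colMeans(abs(attributions$phi))
  ord <- order(-m, names(m))
  data.frame(feature = names(m)[ord], mean_abs_shap = unname(m[ord]))
}

#' Demographic share of the attribution mass
#'
#' Fraction of the total mean |attribution| carried by the five demographic
#' features; defined only for 20-feature models.
#'
#' @param attributions an `attribution_table` over the 20-dim feature set.
#' @return Scalar in `[0, 1]`.
#' @export
demographic_share <- function(attributions) {
  stopifnot(inherits(attributions, "attribution_table"))
  dn <- demographic_feature_names()
  if (!all(dn %in% attributions$feature_names))
    abort("model has no demographic features (15-feature model)")
  m <- colMeans(abs(attributions$phi))
  tot <- sum(m)
  if (tot == 0) return(0)
  sum(m[dn]) / tot
}
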