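# Run configuration ------------------------------------------------------------

#' Pipeline run configuration
#'
#' Houses every tunable of the two-stage pipeline with the published defaults:
#' stage-1 forest of 150 trees with balanced class weights and `sqrt(d)`
#' feature subsampling, ELM with 150 hidden tanh units solved by pseudo-inverse,
#' decision threshold `tau = 0.5`; stage-2 random forest of 700 trees
#' (depth 18, min leaf 2, `d/3` features per split) and the stacked regressor
#' (RF 300/depth 6, XGBoost 300/depth 4/eta 0.05, ELM 250 hidden/alpha 0.2,
#' ridge meta-learner); LOSO fold-exclusion thresholds (target variance 1e-4,
#' minimum 3 test windows).
#'
#' @param window_s stage-2 window length (s).
#' @param sample_window_w stage-1 rolling-statistics window (samples, odd).
#' @param stage1 named list of stage-1 hyperparameters.
#' @param stage2 named list of stage-2 hyperparameters.
#' @param loso named list of fold-exclusion thresholds.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(window_s = 30,
                       sample_window_w = 5,
                       stage1 = list(),
                       stage2 = list(),
                       loso = list(),
                       seed = 1L) {
  s1 <- utils::modifyList(list(
    rf_trees = 150, elm_hidden = 150, elm_alpha = 0, tau = 0.5,
    meta_nrounds = 100, meta_depth = 3, meta_eta = 0.1,
    inner_k = 5, min_gap_samples = 30, train_cap = 15000,
    pred_model = "stacked"), stage1)
  s2 <- utils::modifyList(list(
    rf_trees = 700, rf_depth = 18, rf_min_leaf = 2,
    base_rf_trees = 300, base_rf_depth = 6,
    xgb_rounds = 300, xgb_depth = 4, xgb_eta = 0.05,
    elm_hidden = 250, elm_alpha = 0.2,
    ridge_lambda = 1, inner_k = 5, oof_meta = TRUE), stage2)
  lo <- utils::modifyList(list(var_threshold = 1e-4, min_windows = 3), loso)
  if (s1$tau <= 0 || s1$tau >= 1) abort("tau must lie in (0,1)")
  if (window_s <= 0 || sample_window_w < 1 || sample_window_w %% 2 == 0)
    abort("window_s must be > 0 and sample_window_w odd >= 1")
  if (lo$var_threshold <= 0 || lo$min_windows <= 0) abort("loso thresholds must be > 0")
  structure(list(window_s = window_s, sample_window_w = sample_window_w,
                 stage1 = s1, stage2 = s2, loso = lo, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys are namespaced (`stage1.*`, `stage2.*`, `loso.*`, top-level
#' `window_s`, `sample_window_w`, `seed`); either nested mappings or flat
#' dotted keys are accepted. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(stage1 = list(), stage2 = list(), loso = list())
  for (key in names(raw)) {
    val <- raw[[key]]
    if (key %in% c("stage1", "stage2", "loso") && is.list(val)) {
      out[[key]] <- utils::modifyList(out[[key]], val)
    } else if (grepl("^(stage1|stage2|loso)\\.", key)) {
      ns <- sub("\\..*$", "", key)
      out[[ns]][[sub("^[^.]*\\.", "", key)]] <- val
    } else if (key %in% c("window_s", "sample_window_w", "seed")) {
      out[[key]] <- val
    } else {
      abort("unknown configuration key: %s", key)
    }
  }
  do.call(run_config, out)
}
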