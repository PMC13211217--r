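# evaluation: LOSO harness, metrics, fold filtering, paired statistics --------

#' Leave-one-subject-out folds
#'
#' @param ids character vector of subject ids (>= 2, unique).
#' @return List of `list(train, test)` with one fold per subject; train and
#'   test sets are disjoint and their union is the full cohort.
#' @export
loso_folds <- function(ids) {
  if (length(ids) < 2) abort("LOSO requires >= 2 subjects")
  if (anyDuplicated(ids)) abort("subject ids must be unique")
  lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
}

#' Heel-strike F1 score
#'
#' With `tolerance_samples = 0`, the strict sample-level F1 on the positive
#' class. With a positive tolerance, predicted and true events (positive
#' sample indices) are matched greedily one-to-one within +/- tolerance and
#' F1 is computed over the matching. When neither side has positives the
#' score is defined as 1.
#'
#' @param true_labels,pred_labels equal-length binary vectors.
#' @param tolerance_samples matching tolerance in samples.
#' @return F1 in `[0, 1]`.
#' @export
f1_hs <- function(true_labels, pred_labels, tolerance_samples = 0) {
  if (length(true_labels) != length(pred_labels)) abort("label lengths differ")
  if (tolerance_samples == 0) {
    tp <- sum(true_labels == 1 & pred_labels == 1)
    fp <- sum(true_labels == 0 & pred_labels == 1)
    fn <- sum(true_labels == 1 & pred_labels == 0)
    if (tp + fp + fn == 0) return(1)
    return(2 * tp / (2 * tp + fp + fn))
  }
  event_f1(which(true_labels == 1), which(pred_labels == 1), tolerance_samples)
}

#' Event-level F1 with tolerance matching
#'
#' Greedy one-to-one matching: predicted events are scanned in temporal
#' order; each claims the nearest unmatched true event within
#' `+/- tolerance_samples`.
#'
#' @param true_idx,pred_idx sorted event sample indices.
#' @param tolerance_samples matching tolerance.
#' @return F1 over matched events (1 when both sides are empty).
#' @export
event_f1 <- function(true_idx, pred_idx, tolerance_samples = 3) {
  nt <- length(true_idx)
  np <- length(pred_idx)
  if (nt == 0 && np == 0) return(1)
  if (nt == 0 || np == 0) return(0)
  used <- rep(FALSE, nt)
  tp <- 0L
  for (p in sort(pred_idx)) {
    d <- abs(true_idx - p)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tolerance_samples) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  2 * tp / (np + nt)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the test-set mean as reference; may be negative
#' out of sample. Zero target variance makes the ratio undefined and returns
#' `NA` (the fold-exclusion path).
#'
#' @param y_true,y_pred equal-length numeric vectors (n >= 2).
#' @return R-squared, or `NA` when `Var(y_true) = 0`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  if (length(y_true) < 2) abort("need >= 2 values")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Apply the LOSO fold-exclusion rule
#'
#' VO2 folds with near-zero target variance (`Var(y_test) < var_threshold`)
#' or fewer than `min_windows` test windows are excluded from aggregate
#' statistics; exclusions carry a reason.
#'
#' @param folds data.frame with at least `target_variance` and
#'   `n_test_windows` columns.
#' @param var_threshold,min_windows exclusion thresholds.
#' @return The data.frame with logical `included` and character
#'   `exclusion_reason` columns.
#' @export
filter_folds <- function(folds, var_threshold = 1e-4, min_windows = 3) {
  reason <- rep(NA_character_, nrow(folds))
  reason[folds$n_test_windows < min_windows] <- "min windows"
  reason[is.na(reason) & folds$target_variance < var_threshold] <- "variance"
  folds$included <- is.na(reason)
  folds$exclusion_reason <- reason
  folds
}

#' Aggregate per-fold metrics
#'
#' Median, mean, standard deviation, best and worst over included folds (the
#' median is the headline statistic: it is robust to the low-performing
#' subjects that dominate the mean under LOSO).
#'
#' @param values per-fold metric values.
#' @param included logical inclusion mask (default: all).
#' @return Named list `median, mean, std, best, worst, n_folds`.
#' @export
aggregate_folds <- function(values, included = rep(TRUE, length(values))) {
  v <- values[included & !is.na(values)]
  if (length(v) == 0) abort("no included folds to aggregate")
  list(median = median(v), mean = mean(v), std = stats::sd(v),
       best = max(v), worst = min(v), n_folds = length(v))
}

#' Paired statistics across LOSO folds
#'
#' Two-sided paired t-test, two-sided Wilcoxon signed-rank (zero differences
#' dropped, exact small-sample method where applicable), paired Cohen's
#' d = mean(diff) / sd(diff) (sample sd), and Shapiro-Wilk normality of the
#' differences. Degenerate cases (all differences equal) are flagged rather
#' than erroring.
#'
#' @param values_a,values_b equal-length paired per-fold metric vectors
#'   (length >= 3).
#' @param label_a,label_b condition labels.
#' @return A `paired_comparison` list with `t_p`, `wilcoxon_p`, `cohens_d`,
#'   `shapiro_p`, `delta_median` (median of b minus median of a),
#'   `mean_diff`, `n`, `degenerate`.
#' @export
paired_stats <- function(values_a, values_b, label_a = "A", label_b = "B") {
  if (length(values_a) != length(values_b)) abort("paired vectors differ in length")
  if (length(values_a) < 3) abort("need >= 3 paired folds")
  d <- values_b - values_a
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    t_p <- NA_real_
    cd <- NA_real_
    sh <- NA_real_
    w_p <- if (all(d == 0)) NA_real_ else
      suppressWarnings(stats::wilcox.test(values_b, values_a, paired = TRUE)$p.value)
  } else {
    t_p <- stats::t.test(values_b, values_a, paired = TRUE)$p.value
    w_p <- suppressWarnings(stats::wilcox.test(values_b, values_a,
                                               paired = TRUE)$p.value)
    cd <- mean(d) / stats::sd(d)
    sh <- if (length(unique(d)) > 2) stats::shapiro.test(d)$p.value else NA_real_
  }
  structure(list(condition_a = label_a, condition_b = label_b,
                 values_a = values_a, values_b = values_b,
                 t_p = t_p, wilcoxon_p = w_p, cohens_d = cd, shapiro_p = sh,
                 delta_median = median(values_b) - median(values_a),
                 mean_diff = mean(d), n = length(d), degenerate = degenerate),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired comparison %s vs %s over %d folds>\n", x$condition_a,
              x$condition_b, x$n))
  cat(sprintf("  delta median (%s - %s): %+.4f\n", x$condition_b, x$condition_a,
              x$delta_median))
  if (x$degenerate) {
    cat("  degenerate: all paired differences equal; t and d undefined\n")
  } else {
    cat(sprintf("  paired t p = %.4g, Wilcoxon p = %.4g, Cohen's d = %+.3f, Shapiro p = %.4g\n",
                x$t_p, x$wilcoxon_p, x$cohens_d, x$shapiro_p))
  }
  invisible(x)
}

#' Compare GT-HS and Pred-HS LOSO reports
#'
#' Pairs per-fold R-squared across the two heel-strike sources over the folds
#' included on both sides (intersecting with a warning when the included sets
#' disagree) and reports the median under each source, the delta
#' (Pred minus GT), and the paired statistics.
#'
#' @param report_gt,report_pred `loso_report`s from [run_vo2_loso()] for the
#'   same cohort and model, differing only in `hs_source`.
#' @return List with `median_gt`, `median_pred`, `delta_median`
#'   (Pred - GT) and `stats` (a `paired_comparison`).
#' @export
compare_gt_pred <- function(report_gt, report_pred) {
  fg <- report_gt$folds
  fp <- report_pred$folds
  common <- intersect(fg$held_out_subject[fg$included],
                      fp$held_out_subject[fp$included])
  if (length(common) < length(fg$held_out_subject[fg$included]) ||
      length(common) < length(fp$held_out_subject[fp$included]))
    warning("included fold sets disagree between sources; intersecting")
  a <- fg$metric_value[match(common, fg$held_out_subject)]
  b <- fp$metric_value[match(common, fp$held_out_subject)]
  st <- paired_stats(a, b, "GT-HS", "Pred-HS")
  list(median_gt = median(a), median_pred = median(b),
       delta_median = median(b) - median(a), stats = st,
       common_folds = common)
}
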