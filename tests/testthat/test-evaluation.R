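# LOSO folds, metrics, fold exclusion, paired statistics

test_that("LOSO folds are exhaustive and disjoint", {
  ids <- sprintf("S%02d", 1:24)
  folds <- loso_folds(ids)
  expect_length(folds, 24)
  expect_setequal(vapply(folds, `[[`, character(1), "test"), ids)
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_error(loso_folds("S01"), ">= 2")
  expect_error(loso_folds(c("S01", "S01")), "unique")
})

test_that("F1 matches hand-computed confusion counts", {
  y <- integer(100); y[c(10, 40, 70)] <- 1L
  expect_equal(f1_hs(y, y), 1)
  expect_equal(f1_hs(y, integer(100)), 0)
  # TP = 2, FP = 1, FN = 1 -> F1 = 2/3
  p <- integer(100); p[c(10, 40, 90)] <- 1L
  expect_equal(f1_hs(y, p), 2 / 3)
  # empty on both sides is perfect agreement
  expect_equal(f1_hs(integer(10), integer(10)), 1)

  # tolerance matching is one-to-one and greedy
  expect_equal(event_f1(c(100, 200), c(102, 198), 3), 1)
  expect_equal(event_f1(c(100, 200), c(104, 200), 3), 0.5)
  expect_equal(event_f1(c(100), c(99, 101), 3), 2 * 1 / 3)  # one pred unmatched
  expect_equal(event_f1(integer(0), integer(0), 3), 1)
})

test_that("R-squared follows the test-mean definition and flags zero variance", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_lt(r_squared(y, c(5, 5, 5)), 0)        # can be negative out of sample
  expect_true(is.na(r_squared(c(2, 2, 2), y)))
  expect_error(r_squared(1, 1), ">= 2")
})

test_that("fold exclusion applies the printed variance and count rules", {
  folds <- data.frame(held_out_subject = c("A", "B", "C"),
                      metric_value = c(0.7, 0.1, 0.5),
                      n_test_windows = c(10, 2, 10),
                      target_variance = c(0.5, 0.5, 5e-5))
  out <- filter_folds(folds, 1e-4, 3)
  expect_identical(out$included, c(TRUE, FALSE, FALSE))
  expect_identical(out$exclusion_reason, c(NA, "min windows", "variance"))
})

test_that("aggregates cover median/mean/std/best/worst over included folds", {
  a <- aggregate_folds(c(0.2, 0.6, 0.7))
  expect_equal(a[c("median", "mean", "best", "worst")],
               list(median = 0.6, mean = 0.5, best = 0.7, worst = 0.2))
  expect_equal(aggregate_folds(0.4)$median, 0.4)
  expect_equal(aggregate_folds(c(0.7, 0.2, 0.6))$median, 0.6)  # order-free
  expect_equal(aggregate_folds(c(0.9, 0.1, 0.5), c(TRUE, FALSE, TRUE))$worst, 0.5)
  expect_error(aggregate_folds(c(0.5), FALSE), "no included")

  # median robustness: one catastrophic fold moves the mean, not the median
  base <- c(0.60, 0.62, 0.64, 0.66, 0.68, 0.70, 0.72, 0.74, 0.76)
  spoiled <- c(base[-1], -5)
  expect_equal(median(spoiled), median(base), tolerance = 0.03)
  expect_lt(mean(spoiled), mean(base) - 0.4)
})

test_that("paired statistics agree with textbook oracles to 1e-9", {
  set.seed(50)
  for (i in 1:20) {
    n <- sample(8:24, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, 0.1, 0.5)
    ps <- paired_stats(a, b)
    d <- b - a
    tstat <- mean(d) / (sd(d) / sqrt(n))
    expect_lt(abs(ps$t_p - 2 * pt(-abs(tstat), n - 1)), 1e-9)
    r <- rank(abs(d)); v <- sum(r[d > 0])
    w_oracle <- min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
    expect_lt(abs(ps$wilcoxon_p - w_oracle), 1e-9)
    expect_equal(ps$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
    expect_true(ps$shapiro_p > 0 && ps$shapiro_p <= 1)
  }
})

test_that("degenerate paired comparisons are flagged, not fatal", {
  a <- c(0.5, 0.6, 0.7, 0.8)
  ps <- paired_stats(a, a)
  expect_true(ps$degenerate)
  expect_equal(ps$delta_median, 0)
  expect_true(is.na(ps$t_p))
  ps2 <- paired_stats(a, a + 1)       # sd(diff) = 0 path
  expect_true(ps2$degenerate)
  expect_equal(ps2$delta_median, 1)
  expect_error(paired_stats(a, a[-1]), "length")
  expect_error(paired_stats(a[1:2], a[1:2]), ">= 3")
})

fake_report <- function(vals, ids = sprintf("S%02d", seq_along(vals)),
                        included = rep(TRUE, length(vals))) {
  folds <- data.frame(held_out_subject = ids, task = "VO2",
                      metric_name = "r_squared", metric_value = vals,
                      n_test_windows = 9, target_variance = 1,
                      included = included, exclusion_reason = NA_character_)
  structure(list(folds = folds,
                 aggregates = aggregate_folds(vals, included),
                 model = "rf", hs_source = "GT",
                 include_demographics = FALSE), class = "loso_report")
}

test_that("GT-vs-Pred comparison uses the Pred minus GT convention", {
  g <- fake_report(c(0.60, 0.65, 0.70, 0.75))
  p <- fake_report(c(0.62, 0.70, 0.71, 0.80))
  cmp <- compare_gt_pred(g, p)
  expect_equal(cmp$delta_median, median(p$folds$metric_value) -
                 median(g$folds$metric_value))
  expect_gt(cmp$delta_median, 0)
  expect_identical(cmp$stats$condition_b, "Pred-HS")

  # identical reports give a flagged zero-delta comparison
  cmp0 <- compare_gt_pred(g, g)
  expect_equal(cmp0$delta_median, 0)
  expect_true(cmp0$stats$degenerate)

  # disagreeing inclusion sets intersect with a warning
  p2 <- fake_report(c(0.62, 0.70, 0.71, 0.80),
                    included = c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(cmp2 <- compare_gt_pred(g, p2), "intersect")
  expect_length(cmp2$common_folds, 3)
})
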