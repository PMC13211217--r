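# heel-strike classifiers, ensembling, event consolidation

# separable toy: positive iff x1 + x2 > 1.5, with subject grouping
toy_hs_data <- function(n = 600, seed = 20) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] + x[, 2] > 1.5)
  list(x = x, y = y, subject = rep(sprintf("S%02d", 1:6), length.out = n))
}

test_that("balanced class weights follow N / (2 Nc)", {
  expect_equal(balanced_class_weights(rep(c(0, 1), 20)),
               c("0" = 1, "1" = 1))
  labs <- c(rep(1, 10), rep(0, 30))
  w <- balanced_class_weights(labs)
  expect_equal(unname(w["1"]), 2.0)
  expect_equal(unname(w["0"]), 40 / 60)
  expect_error(balanced_class_weights(rep(0, 5)), "both classes")
})

test_that("random forest learns a separable rule and exposes OOB error", {
  d <- toy_hs_data()
  rf <- fit_rf_hs(d$x, d$y, trees = 100, seed = 1)
  expect_true(is.finite(rf$oob_error))
  p <- predict_rf_proba(rf, d$x)
  expect_gt(f1_hs(d$y, classify_hs(p, 0.5)), 0.9)
})

test_that("ELM+RF ensemble is the unweighted probability mean", {
  d <- toy_hs_data()
  rf <- fit_rf_hs(d$x, d$y, trees = 60, seed = 2)
  elm <- fit_elm_hs(d$x, d$y, n_hidden = 40, seed = 3)
  p <- predict_ensemble_elm_rf(rf, elm, d$x)
  expect_equal(p, (predict_rf_proba(rf, d$x) + predict_elm_proba(elm, d$x)) / 2)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("thresholding detects at the boundary and sweeps monotonically", {
  expect_identical(classify_hs(0.5, 0.5), 1L)
  expect_identical(classify_hs(rep(0, 5), 0.5), rep(0L, 5))
  set.seed(21)
  p <- runif(200)
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(t) sum(classify_hs(p, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("event consolidation collapses runs and enforces the refractory gap", {
  # isolated positives far apart are untouched
  lab <- integer(500)
  lab[c(50, 150, 250)] <- 1L
  ev <- consolidate_events(lab, 30)
  expect_identical(ev$event_indices, c(50L, 150L, 250L))

  # run of 5 positives collapses to its central sample
  lab2 <- integer(100)
  lab2[41:45] <- 1L
  expect_identical(consolidate_events(lab2, 30)$event_indices, 43L)

  # two events 10 samples apart merge, keeping the higher probability
  lab3 <- integer(100)
  lab3[c(40, 50)] <- 1L
  p <- rep(0, 100); p[40] <- 0.7; p[50] <- 0.9
  expect_identical(consolidate_events(lab3, 30, p)$event_indices, 50L)
  # without probabilities the earlier one wins
  expect_identical(consolidate_events(lab3, 30)$event_indices, 40L)

  # property: output strictly increasing with pairwise gaps >= min_gap
  set.seed(22)
  for (i in 1:20) {
    lab4 <- as.integer(runif(400) < 0.1)
    evi <- consolidate_events(lab4, 25)$event_indices
    if (length(evi) > 1) {
      expect_true(all(diff(evi) > 0))
      expect_true(all(diff(evi) >= 25))
    }
  }
})

test_that("stacked classifier uses 2 meta-features and nails a separable toy", {
  d <- toy_hs_data(800, seed = 23)
  m <- fit_stacked_hs(d$x, d$y, d$subject, run_config(), seed = 5)
  expect_equal(m$tau, 0.5)
  expect_identical(class(m), "hs_stacked")
  # the meta-learner consumes exactly the two base probabilities
  expect_equal(xgboost::xgb.importance(model = m$meta)$Feature %in%
                 c("p_rf", "p_elm"), rep(TRUE, nrow(xgboost::xgb.importance(model = m$meta))))
  p <- predict_stacked_hs(m, d$x)
  expect_equal(f1_hs(d$y, classify_hs(p, m$tau)), 1.0, tolerance = 0.02)
  expect_error(fit_stacked_hs(d$x, d$y, rep("S1", nrow(d$x)), run_config()),
               ">= 2")
})
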