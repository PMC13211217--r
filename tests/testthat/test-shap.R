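# TreeSHAP attributions

test_that("attributions satisfy local accuracy on the random forest", {
  set.seed(60)
  n <- 150; d <- 6
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("v", 1:d)))
  y <- 2 * x[, 1] + x[, 2]^2 + rnorm(n, 0, 0.2)
  rf <- fit_rf_regressor(x, y, trees = 150, max_depth = 12, seed = 1)
  att <- shap_attributions(rf, x[1:100, ])
  expect_lt(max(abs(att$base_value + rowSums(att$phi) -
                      predict(rf, x[1:100, ]))), 1e-6)
})

test_that("attributions on a boosted model match its native TreeSHAP", {
  set.seed(61)
  n <- 150; d <- 7
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("v", 1:d)))
  y <- x[, 1] - 0.5 * x[, 3] + rnorm(n, 0, 0.2)
  xm <- fit_xgb_regressor(x, y, nrounds = 50, max_depth = 4, eta = 0.2, seed = 2)
  att <- shap_attributions(xm, x[1:60, ])
  ref <- predict(xm$model, xgboost::xgb.DMatrix(x[1:60, ]), predcontrib = TRUE)
  expect_lt(max(abs(att$phi - ref[, 1:d])), 1e-4)
  expect_lt(abs(att$base_value - ref[1, d + 1]), 1e-6)
})

test_that("features that never vary receive zero attribution", {
  set.seed(62)
  n <- 120
  x <- cbind(sig = rnorm(n), flat1 = rep(1, n), flat2 = rep(-2, n))
  y <- 3 * x[, "sig"] + rnorm(n, 0, 0.1)
  rf <- fit_rf_regressor(x, y, trees = 100, seed = 3)
  att <- shap_attributions(rf, x[1:50, ])
  expect_true(all(att$phi[, c("flat1", "flat2")] == 0))
  expect_gt(mean(abs(att$phi[, "sig"])), 0)
})

test_that("a planted acc_std-driven target ranks acc_std first", {
  co <- cached("shap_cohort", {
    generate_cohort(4, sim_config(stages = graded_walk_protocol(60)[1:2],
                                  seed = 63))
  })
  tabs <- do.call(rbind, cohort_window_tables(co, "gt", TRUE))
  fcols <- stage2_feature_names(TRUE)
  x <- as.matrix(tabs[, fcols])
  # break the natural correlation with co-moving kinematic features so the
  # planted signal lives in acc_std alone
  set.seed(64)
  for (j in setdiff(colnames(x), "acc_std")) x[, j] <- sample(x[, j])
  y <- 5 * x[, "acc_std"] + rnorm(nrow(x), 0, 1e-3)
  rf <- fit_rf_regressor(x, y, trees = 200, seed = 4)
  rk <- importance_ranking(shap_attributions(rf, x))
  expect_identical(rk$feature[1], "acc_std")
  expect_equal(rk$mean_abs_shap,
               unname(sort(colMeans(abs(shap_attributions(rf, x)$phi)),
                           decreasing = TRUE)))
})

test_that("demographic share tracks where the signal lives", {
  co <- cached("shap_cohort", {
    generate_cohort(4, sim_config(stages = graded_walk_protocol(60)[1:2],
                                  seed = 63))
  })
  tabs <- do.call(rbind, cohort_window_tables(co, "gt", TRUE))
  fcols <- stage2_feature_names(TRUE)
  x <- as.matrix(tabs[, fcols])

  # constant demographics cannot carry attribution mass
  xc <- x
  for (nm in demographic_feature_names()) xc[, nm] <- mean(xc[, nm])
  set.seed(65)
  yk <- 2 * xc[, "intensity"] + rnorm(nrow(xc), 0, 0.05)
  rf <- fit_rf_regressor(xc, yk, trees = 150, seed = 5)
  att <- shap_attributions(rf, xc)
  expect_lt(demographic_share(att), 0.05)

  # a BMI-driven target concentrates mass on demographics
  yd <- 0.5 * x[, "bmi"] + rnorm(nrow(x), 0, 0.05)
  rfd <- fit_rf_regressor(x, yd, trees = 150, seed = 6)
  expect_gt(demographic_share(shap_attributions(rfd, x)), 0.5)

  # 15-feature models have no demographic share
  rf15 <- fit_rf_regressor(x[, stage2_feature_names(FALSE)], yk, trees = 50,
                           seed = 7)
  expect_error(demographic_share(shap_attributions(rf15, x[, stage2_feature_names(FALSE)])),
               "demographic")
})

test_that("importance ranking is order-invariant with alphabetical ties", {
  att <- structure(list(phi = matrix(0, 10, 3,
                                     dimnames = list(NULL, c("c", "a", "b"))),
                        feature_names = c("c", "a", "b")),
                   class = "attribution_table")
  rk <- importance_ranking(att)
  expect_identical(rk$feature, c("a", "b", "c"))
  expect_identical(rk$mean_abs_shap, rep(0, 3))

  set.seed(66)
  phi <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  att2 <- structure(list(phi = phi, feature_names = colnames(phi)),
                    class = "attribution_table")
  att3 <- structure(list(phi = phi[sample(20), ], feature_names = colnames(phi)),
                    class = "attribution_table")
  expect_identical(importance_ranking(att2), importance_ranking(att3))
  expect_equal(importance_ranking(att2)$mean_abs_shap,
               unname(sort(colMeans(abs(phi)), decreasing = TRUE)))
})
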