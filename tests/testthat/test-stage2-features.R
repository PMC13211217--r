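# 30 s windowing, window features, targets

test_that("windows tile the recording without gaps or overlap", {
  rec <- make_record(matrix(rnorm(60000 * 3), ncol = 3),
                     matrix(rnorm(60000 * 3), ncol = 3))
  w <- segment_windows(rec, 30)
  expect_identical(nrow(w), 20L)
  expect_true(all(w$end - w$start + 1L == 3000L))
  expect_identical(w$start[-1], w$end[-20] + 1L)
  expect_identical(w$start[1], 1L)

  rec2 <- make_record(matrix(0, 3050, 3), matrix(0, 3050, 3))
  expect_identical(nrow(segment_windows(rec2, 30)), 1L)
  rec3 <- make_record(matrix(0, 100, 3), matrix(0, 100, 3))
  expect_error(segment_windows(rec3, 30), "shorter")
})

test_that("kinematic features match closed forms and a brute-force oracle", {
  fs <- 100
  # constant magnitude c on the z axis
  c0 <- 1.7
  kin <- kinematic_window_features(cbind(0, 0, rep(c0, 300)),
                                  matrix(0, 300, 3), fs)
  expect_equal(unname(kin[c("acc_mean", "acc_rms")]), c(c0, c0))
  expect_equal(unname(kin[c("acc_std", "acc_range", "jerk_rms")]), c(0, 0, 0))
  expect_equal(unname(kin["intensity"]), c0)

  # alternating two-valued magnitude
  a <- 1; b <- 2
  alt <- rep(c(a, b), 150)
  kin2 <- kinematic_window_features(cbind(0, 0, alt), matrix(0, 300, 3), fs)
  expect_equal(unname(kin2["acc_mean"]), (a + b) / 2)
  expect_equal(unname(kin2["jerk_rms"]), abs(a - b) * fs)

  # random window against explicit formula evaluation
  set.seed(30)
  acc <- matrix(rnorm(900), 300, 3)
  gyro <- matrix(rnorm(900, sd = 30), 300, 3)
  k <- kinematic_window_features(acc, gyro, fs)
  am <- sqrt(rowSums(acc^2)); gm <- sqrt(rowSums(gyro^2))
  nw <- length(am)
  oracle <- c(sum(am) / nw,
              sqrt(sum((am - mean(am))^2) / nw),
              sqrt(sum(am^2) / nw),
              max(am) - min(am),
              sqrt(sum((gm - mean(gm))^2) / nw),
              sqrt(sum(gm^2) / nw),
              sqrt(sum(((am[-1] - am[-nw]) * fs)^2) / (nw - 1)),
              sqrt(sum(am^2) / nw))
  expect_lt(max(abs(unname(k) - oracle)), 1e-10)
})

test_that("spectral features locate tones and band energy", {
  fs <- 100; t <- (0:2999) / fs
  s2 <- sin(2 * pi * 2 * t)
  sp <- spectral_window_features(s2, fs)
  expect_lt(abs(sp["dom_freq_hz"] - 2.0), fs / 256 + 1e-9)

  # a 10 Hz tone leaves almost nothing in the 0.5-3 Hz band
  s10 <- sin(2 * pi * 10 * t)
  w <- welch_psd(s10, fs)
  total <- sum(w$psd) * fs / 256
  expect_lt(unname(spectral_window_features(s10, fs)["bandpower"]), 0.01 * total)

  # power scales with amplitude squared
  f1 <- spectral_window_features(s2, fs)["bandpower"]
  f2 <- spectral_window_features(2 * s2, fs)["bandpower"]
  expect_equal(unname(f2 / f1), 4, tolerance = 1e-6)
  expect_error(welch_psd(rnorm(100), fs), "shorter")
})

test_that("gait temporal features follow the printed formulas", {
  g <- gait_temporal_features(seq(1, 3000, length.out = 40), 30, 100)
  expect_equal(unname(g["cadence_spm"]), 80)
  expect_equal(unname(g["step_freq_hz"]), 40 / 30)
  expect_equal(unname(g["n_hs"]), 40)

  # uniform strides of 0.75 s
  g2 <- gait_temporal_features(seq(0, 2925, by = 75), 30, 100)
  expect_equal(unname(g2["stride_mean_s"]), 0.75)
  expect_equal(unname(g2["stride_std_s"]), 0)

  # irregular events: deltas (0.5, 1.1, 1.4) s, sd with divisor N_HS - 1
  g3 <- gait_temporal_features(c(0, 50, 160, 300), 30, 100)
  expect_equal(unname(g3["stride_mean_s"]), 1.0)
  expect_equal(unname(g3["stride_std_s"]), sqrt((0.25 + 0.01 + 0.16) / 3),
               tolerance = 1e-12)
  expect_equal(round(unname(g3["stride_std_s"]), 4), 0.3742)

  # fewer than two events: stride features are 0, not missing
  g4 <- gait_temporal_features(c(17), 30, 100)
  expect_equal(unname(g4[c("stride_mean_s", "stride_std_s")]), c(0, 0))
})

test_that("composite intensity is the acc-RMS x cadence product", {
  expect_equal(composite_intensity(1.0, 80), 80)
  expect_equal(composite_intensity(0.7, 0), 0)
  expect_equal(composite_intensity(2 * 0.7, 90), 2 * composite_intensity(0.7, 90))
  expect_error(composite_intensity(-1, 80), ">= 0")
})

test_that("demographics vector uses M=1/F=0 coding and the BMI identity", {
  d <- demographics(25, 165.1, 62.3, "F")
  v <- demographics_vector(d)
  expect_equal(unname(v["bmi"]), 62.3 / 1.651^2, tolerance = 1e-12)
  expect_equal(round(unname(v["bmi"]), 3), 22.856)
  expect_equal(unname(v["gender"]), 0)
  expect_equal(unname(demographics_vector(demographics(25, 165.1, 62.3, "M"))["gender"]), 1)
  expect_error(demographics(25, 0, 62.3, "F"), "height")
})

test_that("VO2 normalization is the epsilon-guarded per-subject z-score", {
  rec <- tiny_record(51)
  rec$vo2$vo2 <- rep(12, nrow(rec$vo2))
  st <- vo2_norm_stats(rec)
  expect_equal(normalize_vo2(rec$vo2$vo2, st), rep(0, nrow(rec$vo2)))

  st2 <- list(mu = 5, sigma = 1)
  expect_equal(normalize_vo2(c(4, 6), st2), c(-1, 1), tolerance = 1e-5)
  # population statistics over the full series
  rec$vo2$vo2 <- c(4, 6, rep(5, nrow(rec$vo2) - 2))
  st3 <- vo2_norm_stats(rec)
  expect_equal(st3$mu, mean(rec$vo2$vo2))
  expect_equal(st3$sigma, sqrt(mean((rec$vo2$vo2 - st3$mu)^2)))
})

test_that("targets come from the subsequent 30 s and drop uncovered windows", {
  rec <- make_record(matrix(0, 9000, 3), matrix(0, 9000, 3),
                     vo2 = data.frame(time_s = 45, vo2 = 20))
  win <- segment_windows(rec, 30)
  st <- list(mu = 10, sigma = 5)
  tg <- align_targets(win, rec$vo2, st, 100, 30)
  expect_equal(tg[1], (20 - 10) / (5 + 1e-6))   # breath at t+45 of window 1
  expect_true(is.na(tg[2]) && is.na(tg[3]))

  # constant VO2 makes every defined target (approximately) zero
  rec2 <- tiny_record(52)
  rec2$vo2$vo2 <- rep(15, nrow(rec2$vo2))
  wt <- build_window_table(rec2, "gt")
  expect_true(all(abs(wt$target_vo2_norm) < 1e-9))
  # final window has no subsequent breaths and is dropped
  expect_lt(max(wt$window_index), nrow(segment_windows(rec2, 30)))
})

test_that("window tables share everything but gait features across sources", {
  rec <- tiny_record(53)
  expect_error(build_window_table(rec, "pred"), "hs_pred")
  rec$hs_pred <- rec$hs_gt
  gt <- build_window_table(rec, "gt")
  pr <- build_window_table(rec, "pred")
  expect_identical(dim(gt), dim(pr))
  expect_equal(gt[, setdiff(names(gt), "hs_source")],
               pr[, setdiff(names(pr), "hs_source")], ignore_attr = TRUE)

  # only f7-f11 can differ once predictions diverge
  rec$hs_pred <- integer(length(rec$hs_gt))
  rec$hs_pred[seq(1, length(rec$hs_gt), by = 120)] <- 1L
  pr2 <- build_window_table(rec, "pred")
  shared <- c("acc_mean", "acc_std", "acc_rms", "acc_range", "gyro_std",
              "gyro_rms", "jerk_rms", "dom_freq_hz", "bandpower", "intensity")
  expect_equal(gt[, shared], pr2[, shared], ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(gt$n_hs, pr2$n_hs)))

  # dimension contract and internal consistency
  expect_length(intersect(stage2_feature_names(FALSE), names(gt)), 15)
  wt20 <- build_window_table(rec, "gt", include_demographics = TRUE)
  expect_length(intersect(stage2_feature_names(TRUE), names(wt20)), 20)
  expect_equal(gt$cadence_spm, 60 * gt$step_freq_hz)
  expect_equal(gt$cadence_spm, gt$n_hs * 2)
  expect_true(all(is.finite(as.matrix(gt[, stage2_feature_names(FALSE)]))))
})
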