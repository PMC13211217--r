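# stage1_features: 15-dimensional per-sample feature vector -------------------
#
# Per sample t the feature vector is
#   [acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z,
#    a(t), w(t), da(t), dw(t),
#    mu_a, sigma_a, max_a, min_a, range_a]  in R^15
# where a(t), w(t) are the accelerometer/gyroscope magnitudes, da/dw their
# first-order finite differences, and the last five are rolling statistics of
# the accelerometer magnitude over a centered window of w samples.

#' Euclidean magnitude of a tri-axial signal
#'
#' @param x,y,z equal-length channel vectors.
#' @return `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
signal_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    abort("channel lengths differ")
  sqrt(x^2 + y^2 + z^2)
}

#' First-order finite difference
#'
#' `out[t] = (s[t] - s[t-1]) / dt` for `t >= 2`; the derivative at the first
#' sample is undefined and set to 0 so that N samples map to N rows.
#'
#' @param series numeric vector of length >= 2.
#' @param dt sample spacing (> 0).
#' @return Per-sample derivative, same length as `series`.
#' @export
finite_difference <- function(series, dt) {
  if (dt <= 0) abort("dt must be > 0")
  if (length(series) < 2) abort("series must have length >= 2")
  c(0, diff(series) / dt)
}

#' Centered rolling statistics
#'
#' Mean, population standard deviation, max, min and range over a centered
#' window of `w` samples, truncated at the recording edges (no padding): the
#' first and last `(w-1)/2` rows use correspondingly shorter windows.
#'
#' @param series numeric vector.
#' @param w odd window width >= 1.
#' @return List with vectors `mean`, `std`, `max`, `min`, `range`.
#' @export
rolling_stats <- function(series, w = 5) {
  if (length(series) == 0) abort("series is empty")
  if (w < 1 || w %% 2 == 0) abort("w must be odd and >= 1")
  n <- length(series)
  half <- (w - 1) / 2
  # N x w matrix of neighbors, NA outside the recording
  offs <- (-half):half
  mat <- vapply(offs, function(o) {
    idx <- seq_len(n) + o
    out <- rep(NA_real_, n)
    ok <- idx >= 1 & idx <= n
    out[ok] <- series[idx[ok]]
    out
  }, numeric(n))
  mat <- matrix(mat, nrow = n, ncol = length(offs))
  cnt <- rowSums(!is.na(mat))
  mu <- rowSums(mat, na.rm = TRUE) / cnt
  sig <- sqrt(pmax(0, rowSums((mat - mu)^2, na.rm = TRUE) / cnt))
  mx <- do.call(pmax, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]), na.rm = TRUE))
  mn <- do.call(pmin, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]), na.rm = TRUE))
  list(mean = mu, std = sig, max = mx, min = mn, range = mx - mn)
}

#' Stage-1 feature column names, in order
#' @return Character vector of 15 names.
#' @export
stage1_feature_names <- function() {
  c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
    "acc_mag", "gyro_mag", "d_acc_mag", "d_gyro_mag",
    "roll_mean", "roll_std", "roll_max", "roll_min", "roll_range")
}

#' Build the per-sample stage-1 feature matrix
#'
#' @param record a `subject_record`.
#' @param w rolling-statistics window (odd, default 5 samples).
#' @return List with `values` (N x 15 matrix, columns in the fixed order of
#'   [stage1_feature_names()]) and `labels` (the N binary heel-strike ground
#'   truth), class `sample_features`.
#' @export
build_sample_features <- function(record, w = 5) {
  stopifnot(inherits(record, "subject_record"))
  dt <- 1 / record$sampling_rate_hz
  a <- signal_magnitude(record$acc[, 1], record$acc[, 2], record$acc[, 3])
  g <- signal_magnitude(record$gyro[, 1], record$gyro[, 2], record$gyro[, 3])
  rs <- rolling_stats(a, w)
  values <- cbind(record$acc, record$gyro,
                  acc_mag = a, gyro_mag = g,
                  d_acc_mag = finite_difference(a, dt),
                  d_gyro_mag = finite_difference(g, dt),
                  roll_mean = rs$mean, roll_std = rs$std,
                  roll_max = rs$max, roll_min = rs$min, roll_range = rs$range)
  colnames(values) <- stage1_feature_names()
  structure(list(values = values, labels = record$hs_gt,
                 subject_id = record$subject_id),
            class = "sample_features")
}
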