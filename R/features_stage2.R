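# stage2_features: 30 s window features and the normalized VO2 target ---------
#
# Per non-overlapping 30 s window (N_w = 3000 samples at 100 Hz) a 15-dim
# feature vector f1..f15 is computed (accelerometer/gyroscope magnitude
# statistics, heel-strike-derived gait temporal features, jerk RMS, Welch
# spectral descriptors, intensity = acc RMS), optionally extended with five
# demographics (age, height, weight, gender code, BMI) to d = 20. The target
# is the per-subject z-normalized VO2 averaged over the subsequent 30 s.

#' Stage-2 feature names
#' @param include_demographics append the five demographic names.
#' @return Character vector of 15 or 20 names.
#' @export
stage2_feature_names <- function(include_demographics = FALSE) {
  f <- c("acc_mean", "acc_std", "acc_rms", "acc_range", "gyro_std", "gyro_rms",
         "n_hs", "cadence_spm", "step_freq_hz", "stride_mean_s", "stride_std_s",
         "jerk_rms", "dom_freq_hz", "bandpower", "intensity")
  if (include_demographics) c(f, demographic_feature_names()) else f
}

#' @rdname stage2_feature_names
#' @export
demographic_feature_names <- function() {
  c("age", "height_cm", "weight_kg", "gender", "bmi")
}

#' Segment a recording into non-overlapping windows
#'
#' @param record a `subject_record`.
#' @param window_s window length in seconds.
#' @return data.frame with 1-based inclusive sample bounds `start`, `end`,
#'   each window exactly `window_s * sampling_rate_hz` samples; a trailing
#'   partial window is dropped.
#' @export
segment_windows <- function(record, window_s = 30) {
  nw <- as.integer(round(window_s * record$sampling_rate_hz))
  n_win <- floor(length(record$time_s) / nw)
  if (n_win < 1) abort("recording shorter than one %gs window", window_s)
  data.frame(start = (seq_len(n_win) - 1L) * nw + 1L, end = seq_len(n_win) * nw)
}

#' Kinematic window features
#'
#' f1 = mean(a), f2 = population std(a), f3 = RMS(a), f4 = range(a),
#' f5 = population std(w), f6 = RMS(w) of the accelerometer/gyroscope
#' magnitudes; f12 = RMS of the N_w - 1 jerk finite differences (divisor
#' N_w - 1); f15 = intensity = acc RMS.
#'
#' @param acc N x 3 accelerometer window, g units.
#' @param gyro N x 3 gyroscope window, deg/s.
#' @param fs sampling rate (Hz).
#' @return Named vector `acc_mean, acc_std, acc_rms, acc_range, gyro_std,
#'   gyro_rms, jerk_rms, intensity`.
#' @export
kinematic_window_features <- function(acc, gyro, fs) {
  a <- signal_magnitude(acc[, 1], acc[, 2], acc[, 3])
  w <- signal_magnitude(gyro[, 1], gyro[, 2], gyro[, 3])
  acc_rms <- sqrt(mean(a^2))
  jerk <- diff(a) * fs
  c(acc_mean = mean(a), acc_std = pop_sd(a), acc_rms = acc_rms,
    acc_range = max(a) - min(a), gyro_std = pop_sd(w),
    gyro_rms = sqrt(mean(w^2)), jerk_rms = sqrt(mean(jerk^2)),
    intensity = acc_rms)
}

#' Welch power spectral density
#'
#' Hann-tapered (periodic window) segments of length `nperseg` with 50%
#' overlap, per-segment mean removal, one-sided density scaling
#' (`2 |X|^2 / (fs * sum(w^2))`, DC and Nyquist bins not doubled), averaged
#' over segments.
#'
#' @param x numeric signal (length >= `nperseg`).
#' @param fs sampling rate (Hz).
#' @param nperseg segment length.
#' @param overlap fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd` (power density, unit^2/Hz).
#' @export
welch_psd <- function(x, fs = 100, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) abort("signal shorter than one Welch segment (%d)", nperseg)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  k <- 0:(nperseg - 1)
  win <- 0.5 - 0.5 * cos(2 * pi * k / nperseg)
  norm <- fs * sum(win^2)
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / norm
    sp[2:(nfreq - 1)] <- 2 * sp[2:(nfreq - 1)]
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = acc / length(starts))
}

#' Spectral window features
#'
#' f13 = dominant frequency: argmax of the Welch PSD of the accelerometer
#' magnitude over the full Nyquist range excluding the DC bin (the gravity
#' offset dominates bin 0); f14 = band power, the PSD summed over
#' `[0.5, 3.0]` Hz times the bin width.
#'
#' @param acc_magnitude accelerometer magnitude over one window.
#' @param fs sampling rate (Hz).
#' @param nperseg Welch segment length.
#' @return Named vector `dom_freq_hz`, `bandpower`.
#' @export
spectral_window_features <- function(acc_magnitude, fs = 100, nperseg = 256) {
  w <- welch_psd(acc_magnitude, fs = fs, nperseg = nperseg)
  keep <- -1L                                   # drop DC
  dom <- w$freq[keep][which.max(w$psd[keep])]
  df <- fs / nperseg
  band <- w$freq >= 0.5 & w$freq <= 3.0
  c(dom_freq_hz = dom, bandpower = sum(w$psd[band]) * df)
}

#' Gait temporal window features from heel-strike events
#'
#' f7 = N_HS events in the window; f8 = cadence = N_HS / T * 60 steps/min;
#' f9 = step frequency = N_HS / T Hz; stride intervals
#' `delta_k = (t_{k+1} - t_k) / fs`; f10/f11 = stride mean and standard
#' deviation with divisor N_HS - 1, both 0 when fewer than two events.
#'
#' @param event_idx sample indices of heel strikes inside the window.
#' @param window_len_s window duration T in seconds.
#' @param fs sampling rate (Hz).
#' @return Named vector `n_hs, cadence_spm, step_freq_hz, stride_mean_s,
#'   stride_std_s`.
#' @export
gait_temporal_features <- function(event_idx, window_len_s, fs) {
  n_hs <- length(event_idx)
  cad <- n_hs / window_len_s * 60
  sf <- n_hs / window_len_s
  if (n_hs >= 2) {
    delta <- diff(sort(event_idx)) / fs
    sm <- sum(delta) / (n_hs - 1)
    ss <- sqrt(sum((delta - sm)^2) / (n_hs - 1))
  } else {
    sm <- 0
    ss <- 0
  }
  c(n_hs = n_hs, cadence_spm = cad, step_freq_hz = sf,
    stride_mean_s = sm, stride_std_s = ss)
}

#' Composite mechanical intensity
#'
#' Product of accelerometer RMS and cadence; reported in gait summaries as a
#' composite kinematic proxy for exercise intensity (the window feature f15
#' itself is the plain acc RMS).
#'
#' @param acc_rms accelerometer RMS (g).
#' @param cadence_spm cadence (steps/min).
#' @return `acc_rms * cadence_spm`.
#' @export
composite_intensity <- function(acc_rms, cadence_spm) {
  if (any(acc_rms < 0) || any(cadence_spm < 0)) abort("inputs must be >= 0")
  acc_rms * cadence_spm
}

#' Demographic feature vector
#'
#' `(age, height_cm, weight_kg, gender01, bmi)` with gender coded M = 1,
#' F = 0 and `bmi = weight / height_m^2`.
#'
#' @param demo a [demographics()].
#' @return Named numeric vector of 5 values.
#' @export
demographics_vector <- function(demo) {
  stopifnot(inherits(demo, "demographics"))
  c(age = demo$age, height_cm = demo$height_cm, weight_kg = demo$weight_kg,
    gender = as.numeric(demo$gender == "M"),
    bmi = demo$weight_kg / (demo$height_cm / 100)^2)
}

#' Per-subject VO2 normalization statistics
#'
#' Mean and population standard deviation over the subject's entire VO2
#' series.
#'
#' @param record a `subject_record` with a non-empty VO2 series.
#' @return List `mu`, `sigma` (mL/kg/min).
#' @export
vo2_norm_stats <- function(record) {
  v <- record$vo2$vo2
  if (length(v) == 0) abort("subject %s has no VO2 samples", record$subject_id)
  list(mu = mean(v), sigma = pop_sd(v))
}

#' Normalize a VO2 series
#'
#' `(v - mu) / (sigma + 1e-6)`; the epsilon guards constant series.
#'
#' @param vo2_values numeric VO2 values (mL/kg/min).
#' @param stats list with `mu` and `sigma` from [vo2_norm_stats()].
#' @return Dimensionless normalized values.
#' @export
normalize_vo2 <- function(vo2_values, stats) {
  (vo2_values - stats$mu) / (stats$sigma + 1e-6)
}

#' Align normalized VO2 targets to feature windows
#'
#' The target for the window covering `[t, t + T)` is the mean of the
#' normalized VO2 samples with timestamps in the subsequent interval
#' `[t + T, t + 2T)`; windows with no breath sample there get `NA` (and are
#' dropped by [build_window_table()]).
#'
#' @param windows data.frame from [segment_windows()].
#' @param vo2 data.frame `time_s`, `vo2`.
#' @param stats normalization statistics of the same subject.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @return Numeric vector of per-window targets (NA where undefined).
#' @export
align_targets <- function(windows, vo2, stats, fs, window_s = 30) {
  vnorm <- normalize_vo2(vo2$vo2, stats)
  vapply(seq_len(nrow(windows)), function(i) {
    t0 <- (windows$start[i] - 1) / fs
    sel <- vo2$time_s >= t0 + window_s & vo2$time_s < t0 + 2 * window_s
    if (!any(sel)) NA_real_ else mean(vnorm[sel])
  }, numeric(1))
}

#' Build the per-window feature table for one subject
#'
#' Windowing is identical for both heel-strike sources; only the gait
#' temporal features f7-f11 can differ between `hs_source = "gt"` and
#' `"pred"`. Windows without a VO2 target (e.g. the final window of a
#' recording) are dropped.
#'
#' @param record a `subject_record` (with `hs_pred` filled when
#'   `hs_source = "pred"`).
#' @param hs_source `"gt"` or `"pred"`: which heel-strike labels feed f7-f11.
#' @param include_demographics append the 5 demographic columns (d = 20).
#' @param window_s window length (s).
#' @param nperseg Welch segment length.
#' @return data.frame with `subject_id`, `window_index`, the feature columns
#'   of [stage2_feature_names()], `target_vo2_norm` and `hs_source`.
#' @export
build_window_table <- function(record, hs_source = c("gt", "pred"),
                               include_demographics = FALSE, window_s = 30,
                               nperseg = 256) {
  hs_source <- match.arg(hs_source)
  hs <- if (hs_source == "gt") record$hs_gt else record$hs_pred
  if (hs_source == "pred" && all(is.na(hs)))
    abort("hs_pred is empty for subject %s; run stage 1 first", record$subject_id)
  hs[is.na(hs)] <- 0L
  fs <- record$sampling_rate_hz
  win <- segment_windows(record, window_s)
  stats <- vo2_norm_stats(record)
  targets <- align_targets(win, record$vo2, stats, fs, window_s)
  hs_idx <- which(hs == 1L)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    sl <- win$start[i]:win$end[i]
    kin <- kinematic_window_features(record$acc[sl, , drop = FALSE],
                                     record$gyro[sl, , drop = FALSE], fs)
    a <- signal_magnitude(record$acc[sl, 1], record$acc[sl, 2], record$acc[sl, 3])
    spec <- spectral_window_features(a, fs, nperseg)
    ev <- hs_idx[hs_idx >= win$start[i] & hs_idx <= win$end[i]]
    gait <- gait_temporal_features(ev, window_s, fs)
    c(kin[c("acc_mean", "acc_std", "acc_rms", "acc_range", "gyro_std", "gyro_rms")],
      gait, jerk_rms = unname(kin["jerk_rms"]), spec,
      intensity = unname(kin["intensity"]))
  })
  feat <- do.call(rbind, rows)
  colnames(feat) <- stage2_feature_names(FALSE)
  df <- data.frame(subject_id = record$subject_id,
                   window_index = seq_len(nrow(win)), feat,
                   check.names = FALSE)
  if (include_demographics) {
    dv <- demographics_vector(record$demographics)
    for (nm in names(dv)) df[[nm]] <- dv[[nm]]
  }
  df$target_vo2_norm <- targets
  df$hs_source <- toupper(hs_source)
  df[!is.na(df$target_vo2_norm), , drop = FALSE]
}
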