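# synthetic treadmill-gait + VO2 simulator ------------------------------------
#
# Generates labeled cohorts with the statistical structure the two-stage
# pipeline assumes: staged treadmill walking, impact-like heel-strike (HS)
# transients in the acceleration magnitude at subject-specific cadence,
# stride-periodic gyroscope oscillation, additive sensor noise, and a VO2
# signal coupled monotonically to movement intensity and cadence with
# first-order on-kinetics and breath-level AR(1) noise.

#' Define one treadmill protocol stage
#'
#' @param duration_s stage duration in seconds (> 0).
#' @param speed_kmh belt speed in km/h.
#' @param incline_pct belt incline in percent (carried as metadata; the
#'   simulator does not model incline-specific biomechanics).
#' @param cadence_spm stepping cadence in steps/min, in `[40, 140]`.
#' @return A `protocol_stage` list.
#' @export
protocol_stage <- function(duration_s, speed_kmh, incline_pct = 0, cadence_spm = 80) {
  if (!is_scalar_num(duration_s) || duration_s <= 0) abort("duration_s must be > 0")
  if (!is_scalar_num(cadence_spm) || cadence_spm < 40 || cadence_spm > 140)
    abort("cadence_spm must lie in [40, 140]")
  structure(list(duration_s = duration_s, speed_kmh = speed_kmh,
                 incline_pct = incline_pct, cadence_spm = cadence_spm),
            class = "protocol_stage")
}

#' Staged graded-walking protocol (Bruce-style)
#'
#' Five stages with speed rising from 2.7 to 6.0 km/h and incline from 0 to
#' 14%, each lasting `stage_duration_s` (180 s by default, i.e. the standard
#' three-minute stages). Stage cadences scale with the square root of belt
#' speed around `base_cadence_spm` at the mid-protocol speed, clipped to
#' `[40, 140]` steps/min.
#'
#' @param stage_duration_s seconds per stage.
#' @param base_cadence_spm subject cadence at the mid-protocol speed.
#' @return List of [protocol_stage()] objects with non-decreasing speeds.
#' @export
graded_walk_protocol <- function(stage_duration_s = 180, base_cadence_spm = 81) {
  speeds <- c(2.7, 4.0, 4.8, 5.5, 6.0)
  inclines <- seq(0, 14, length.out = 5)
  ref <- mean(range(speeds))                      # 4.35 km/h
  cad <- pmin(140, pmax(40, base_cadence_spm * sqrt(speeds / ref)))
  mapply(protocol_stage, duration_s = stage_duration_s, speed_kmh = speeds,
         incline_pct = inclines, cadence_spm = cad, SIMPLIFY = FALSE)
}

#' Simulator configuration
#'
#' Defaults emulate a 100 Hz calf-mounted IMU during graded treadmill walking.
#' Acceleration is in g units, angular velocity in deg/s, VO2 in mL/kg/min.
#'
#' @param sampling_rate_hz IMU sampling rate (Hz).
#' @param stages list of [protocol_stage()]; speeds must be non-decreasing.
#' @param hs_impulse_amplitude peak of the heel-strike transient (g).
#' @param impulse_width_s half-sine impulse width (s).
#' @param osc_freq_hz frequency of the damped post-impact oscillation (Hz).
#' @param osc_decay_s time constant of the post-impact oscillation decay (s).
#' @param step_jitter_frac step-time jitter: Gaussian sd as a fraction of the
#'   stride time, truncated at +/- 10% of the stride.
#' @param noise_sd_acc additive accelerometer noise sd (g).
#' @param noise_sd_gyro additive gyroscope noise sd (deg/s).
#' @param gyro_amplitude_dps stride-periodic gyroscope amplitude (deg/s).
#' @param vo2_baseline resting VO2 (mL/kg/min).
#' @param vo2_intensity_gain gain on the per-stage acceleration-RMS proxy.
#' @param vo2_cadence_gain gain on cadence (mL/kg/min per step/min).
#' @param vo2_tau_s first-order VO2 on-kinetics time constant (s).
#' @param vo2_noise_sd breath-level noise sd (mL/kg/min).
#' @param vo2_ar1 AR(1) coefficient of the breath noise.
#' @param breath_interval_s spacing of breath samples (s).
#' @param seed integer seed; a fixed seed gives bit-identical records.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sampling_rate_hz = 100,
                       stages = graded_walk_protocol(),
                       hs_impulse_amplitude = 2.0,
                       impulse_width_s = 0.05,
                       osc_freq_hz = 10,
                       osc_decay_s = 0.05,
                       step_jitter_frac = 0.03,
                       noise_sd_acc = 0.05,
                       noise_sd_gyro = 5,
                       gyro_amplitude_dps = 80,
                       vo2_baseline = 5,
                       vo2_intensity_gain = 25,
                       vo2_cadence_gain = 0.15,
                       vo2_tau_s = 30,
                       vo2_noise_sd = 0.8,
                       vo2_ar1 = 0.7,
                       breath_interval_s = 3,
                       seed = 1L) {
  if (!is_scalar_num(sampling_rate_hz) || sampling_rate_hz <= 0)
    abort("sampling_rate_hz must be > 0")
  if (length(stages) < 1L) abort("at least one protocol stage is required")
  speeds <- vapply(stages, `[[`, numeric(1), "speed_kmh")
  if (is.unsorted(speeds)) abort("stage speeds must be non-decreasing")
  for (nm in c("hs_impulse_amplitude", "noise_sd_acc", "noise_sd_gyro",
               "vo2_noise_sd", "step_jitter_frac"))
    if (get(nm) < 0) abort("%s must be >= 0", nm)
  structure(mget(names(formals(sim_config))), class = "sim_config")
}

#' Subject demographics
#'
#' @param age years.
#' @param height_cm standing height (cm), > 0.
#' @param weight_kg body mass (kg), > 0.
#' @param gender `"M"` or `"F"`.
#' @return A `demographics` list with derived `bmi` (kg/m^2).
#' @export
demographics <- function(age, height_cm, weight_kg, gender) {
  if (!gender %in% c("M", "F")) abort("gender must be 'M' or 'F'")
  if (height_cm <= 0) abort("height_cm must be > 0")
  if (weight_kg <= 0) abort("weight_kg must be > 0")
  structure(list(age = age, height_cm = height_cm, weight_kg = weight_kg,
                 gender = gender, bmi = weight_kg / (height_cm / 100)^2),
            class = "demographics")
}

#' Default demographic sampling ranges
#'
#' Cohort structure of the modeled study population: 24 healthy adults,
#' 10 male / 14 female, age 21-36 y, height 150-180 cm, weight 44-84 kg.
#'
#' @return Named list of `c(min, max)` ranges and the male proportion.
#' @export
demographic_ranges <- function() {
  list(age = c(21, 36), height_cm = c(150, 180), weight_kg = c(44, 84),
       prop_male = 10 / 24)
}

# kernel of one heel-strike transient at sample resolution:
# half-sine impulse followed by an exponentially damped oscillation
hs_kernel <- function(config) {
  fs <- config$sampling_rate_hz
  w <- max(1L, round(config$impulse_width_s * fs))
  imp <- sin(pi * (seq_len(w) - 0.5) / w)                 # peak 1
  nt <- max(0L, round(4 * config$osc_decay_s * fs))
  tt <- seq_len(nt) / fs
  tail <- 0.4 * exp(-tt / config$osc_decay_s) * sin(2 * pi * config$osc_freq_hz * tt)
  c(imp, tail)
}

#' Generate one synthetic subject record
#'
#' Simulates the full staged protocol for one subject: heel-strike ground
#' truth (`hs_gt` marks exactly one sample per step, steps spaced at
#' 60/cadence seconds with truncated Gaussian jitter), an acceleration
#' magnitude with an impact transient at each heel strike over a 1 g gravity
#' baseline, stride-periodic gyroscope oscillation, additive Gaussian sensor
#' noise, and a breath-sampled VO2 series following first-order on-kinetics
#' toward a per-stage steady state (baseline + intensity gain x per-stage
#' acceleration-RMS proxy + cadence gain x cadence) with AR(1) noise.
#' Identical `(config, demographics, subject_id)` give identical records.
#'
#' @param config a [sim_config()].
#' @param demo a [demographics()].
#' @param subject_id character id.
#' @return A `subject_record`: list with `subject_id`, `sampling_rate_hz`,
#'   `time_s`, `acc` and `gyro` (N x 3 matrices), `hs_gt`, `hs_pred`
#'   (initially `NA`), `vo2` (data.frame `time_s`, `vo2`), `demographics`.
#' @export
generate_subject <- function(config, demo, subject_id = "S01") {
  stopifnot(inherits(config, "sim_config"), inherits(demo, "demographics"))
  fs <- config$sampling_rate_hz
  durs <- vapply(config$stages, `[[`, numeric(1), "duration_s")
  total_s <- sum(durs)
  if (total_s < 30) abort("total protocol duration (%gs) is shorter than one 30 s window", total_s)
  n <- round(total_s * fs)
  time_s <- (seq_len(n) - 1) / fs

  withr::with_seed(config$seed, {
    speeds <- vapply(config$stages, `[[`, numeric(1), "speed_kmh")
    cads <- vapply(config$stages, `[[`, numeric(1), "cadence_spm")
    stage_start <- cumsum(c(0, durs[-length(durs)]))
    # per-stage impulse amplitude scales with relative belt speed
    amp <- config$hs_impulse_amplitude * speeds / max(speeds)

    # --- step times with truncated Gaussian jitter
    step_t <- numeric(0)
    step_amp <- numeric(0)
    for (k in seq_along(config$stages)) {
      stride <- 60 / cads[k]
      t <- stage_start[k] + stride / 2
      end <- stage_start[k] + durs[k]
      while (t < end) {
        step_t <- c(step_t, t)
        step_amp <- c(step_amp, amp[k])
        j <- max(-0.1, min(0.1, rnorm(1, 0, config$step_jitter_frac)))
        t <- t + stride * (1 + j)
      }
    }
    hs_idx <- pmin(n, round(step_t * fs) + 1L)
    hs_gt <- integer(n)
    hs_gt[hs_idx] <- 1L

    # --- per-sample stage index and step frequency
    stage_of <- findInterval(time_s, stage_start)
    f_step <- cads[stage_of] / 60

    # --- accelerometer: gravity on z, small sway on x/y, HS transients on z
    sway <- 0.05 * config$hs_impulse_amplitude
    phase <- cumsum(2 * pi * f_step / fs)
    acc_x <- sway * sin(phase)
    acc_y <- sway * cos(phase)
    acc_z <- rep(1, n)
    ker <- hs_kernel(config)
    for (i in seq_along(hs_idx)) {
      sl <- hs_idx[i]:min(n, hs_idx[i] + length(ker) - 1L)
      acc_z[sl] <- acc_z[sl] + step_amp[i] * ker[seq_along(sl)]
    }
    # --- gyroscope: stride-periodic oscillation, amplitude tracks speed
    g_amp <- config$gyro_amplitude_dps * (0.6 + 0.4 * speeds[stage_of] / max(speeds))
    gyro_x <- g_amp * sin(phase)
    gyro_y <- 0.6 * g_amp * sin(phase + pi / 3)
    gyro_z <- 0.3 * g_amp * cos(phase)

    if (config$noise_sd_acc > 0) {
      acc_x <- acc_x + rnorm(n, 0, config$noise_sd_acc)
      acc_y <- acc_y + rnorm(n, 0, config$noise_sd_acc)
      acc_z <- acc_z + rnorm(n, 0, config$noise_sd_acc)
    }
    if (config$noise_sd_gyro > 0) {
      gyro_x <- gyro_x + rnorm(n, 0, config$noise_sd_gyro)
      gyro_y <- gyro_y + rnorm(n, 0, config$noise_sd_gyro)
      gyro_z <- gyro_z + rnorm(n, 0, config$noise_sd_gyro)
    }

    # --- VO2: first-order lag toward per-stage steady state + AR(1) noise
    step_rate <- cads / 60
    rms_proxy <- amp * sqrt(step_rate * config$impulse_width_s / 2)
    ss <- config$vo2_baseline + config$vo2_intensity_gain * rms_proxy +
      config$vo2_cadence_gain * cads
    bt <- seq(config$breath_interval_s, total_s - 1e-9, by = config$breath_interval_s)
    v <- numeric(length(bt))
    lag_gain <- 1 - exp(-config$breath_interval_s / config$vo2_tau_s)
    cur <- config$vo2_baseline
    for (i in seq_along(bt)) {
      k <- findInterval(bt[i], stage_start)
      cur <- cur + lag_gain * (ss[k] - cur)
      v[i] <- cur
    }
    if (config$vo2_noise_sd > 0) {
      e <- numeric(length(bt))
      innov_sd <- config$vo2_noise_sd * sqrt(1 - config$vo2_ar1^2)
      e[1] <- rnorm(1, 0, config$vo2_noise_sd)
      for (i in seq_along(bt)[-1]) e[i] <- config$vo2_ar1 * e[i - 1] + rnorm(1, 0, innov_sd)
      v <- v + e
    }

    acc <- cbind(acc_x = acc_x, acc_y = acc_y, acc_z = acc_z)
    gyro <- cbind(gyro_x = gyro_x, gyro_y = gyro_y, gyro_z = gyro_z)
    structure(list(subject_id = subject_id, sampling_rate_hz = fs,
                   time_s = time_s, acc = acc, gyro = gyro,
                   hs_gt = hs_gt, hs_pred = rep(NA_integer_, n),
                   vo2 = data.frame(time_s = bt, vo2 = v),
                   demographics = demo),
              class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s: %.0f s @ %g Hz, %d heel strikes, %d breaths>\n",
              x$subject_id, max(x$time_s) + 1 / x$sampling_rate_hz,
              x$sampling_rate_hz, sum(x$hs_gt), nrow(x$vo2)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Samples demographics uniformly within `ranges` (gender by the configured
#' male proportion), draws per-subject gait and metabolic heterogeneity
#' (baseline cadence, impulse amplitude, and VO2 gains) so that
#' leave-one-subject-out folds are non-trivial, and generates each subject
#' with a deterministically derived per-subject seed.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param config a [sim_config()]; its `seed` is the cohort master seed and
#'   its stage durations define the protocol.
#' @param ranges demographic ranges as [demographic_ranges()].
#' @param cadence_mean_spm,cadence_sd_spm inter-subject baseline cadence
#'   distribution (truncated to `[55, 112]` steps/min).
#' @param subject_sd_frac lognormal sd of per-subject multipliers on impulse
#'   amplitude and VO2 gains (0 = identical physiology across subjects).
#' @return A `cohort`: list with `subjects` (list of `subject_record`) and
#'   `sampling_rate_hz`.
#' @export
generate_cohort <- function(n_subjects = 24, config = sim_config(),
                            ranges = demographic_ranges(),
                            cadence_mean_spm = 81, cadence_sd_spm = 12,
                            subject_sd_frac = 0.15) {
  if (n_subjects < 2) abort("n_subjects must be >= 2")
  for (nm in c("age", "height_cm", "weight_kg"))
    if (ranges[[nm]][1] > ranges[[nm]][2]) abort("range for %s has min > max", nm)

  durs <- vapply(config$stages, `[[`, numeric(1), "duration_s")
  subjects <- withr::with_seed(config$seed, {
    lapply(seq_len(n_subjects), function(i) {
      demo <- demographics(
        age = round(runif(1, ranges$age[1], ranges$age[2])),
        height_cm = round(runif(1, ranges$height_cm[1], ranges$height_cm[2]), 1),
        weight_kg = round(runif(1, ranges$weight_kg[1], ranges$weight_kg[2]), 1),
        gender = if (runif(1) < ranges$prop_male) "M" else "F")
      cad <- min(112, max(55, rnorm(1, cadence_mean_spm, cadence_sd_spm)))
      mult <- exp(rnorm(3, 0, subject_sd_frac))
      cfg_i <- config
      cfg_i$stages <- graded_walk_protocol(stage_duration_s = durs[1],
                                           base_cadence_spm = cad)
      # keep the configured number of stages if the default count differs
      cfg_i$stages <- cfg_i$stages[seq_len(min(length(cfg_i$stages), length(durs)))]
      for (k in seq_along(cfg_i$stages)) cfg_i$stages[[k]]$duration_s <- durs[k]
      cfg_i$hs_impulse_amplitude <- config$hs_impulse_amplitude * mult[1]
      cfg_i$vo2_intensity_gain <- config$vo2_intensity_gain * mult[2]
      cfg_i$vo2_cadence_gain <- config$vo2_cadence_gain * mult[3]
      cfg_i$seed <- derive_seed(config$seed, "subject", i)
      generate_subject(cfg_i, demo, sprintf("S%02d", i))
    })
  })
  structure(list(subjects = subjects, sampling_rate_hz = config$sampling_rate_hz),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects @ %g Hz>\n", length(x$subjects), x$sampling_rate_hz))
  invisible(x)
}

#' Subject ids of a cohort
#' @param cohort a `cohort`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "subject_id")
}
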