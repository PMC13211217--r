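# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# short two-stage record: 120 s at 100 Hz, enough for 4 windows / 3 targets
tiny_sim_config <- function(seed = 11, ...) {
  sim_config(stages = graded_walk_protocol(60)[1:2], seed = seed, ...)
}

tiny_record <- function(seed = 11, ...) {
  generate_subject(tiny_sim_config(seed, ...), demographics(25, 170, 65, "M"),
                   sprintf("T%02d", seed %% 100))
}

# hand-built record wrapper for synthetic signal injection
make_record <- function(acc, gyro, fs = 100, hs_gt = NULL, vo2 = NULL,
                        demo = demographics(30, 165, 60, "F"), id = "X01") {
  n <- nrow(acc)
  colnames(acc) <- c("acc_x", "acc_y", "acc_z")
  colnames(gyro) <- c("gyro_x", "gyro_y", "gyro_z")
  if (is.null(hs_gt)) hs_gt <- integer(n)
  if (is.null(vo2)) {
    span <- (n - 1) / fs
    bt <- if (span >= 3) seq(3, span, by = 3) else span / 2
    vo2 <- data.frame(time_s = bt, vo2 = 10 + bt / 60)
  }
  structure(list(subject_id = id, sampling_rate_hz = fs,
                 time_s = (seq_len(n) - 1) / fs, acc = acc, gyro = gyro,
                 hs_gt = hs_gt, hs_pred = rep(NA_integer_, n), vo2 = vo2,
                 demographics = demo),
            class = "subject_record")
}

# small end-to-end pipeline reused across files (pipeline + determinism tests)
small_pipeline_runs <- function() {
  cached("small_pipeline", {
    run_once <- function() {
      cfg <- sim_config(stages = graded_walk_protocol(60)[1:2], seed = 404)
      co <- generate_cohort(4, cfg)
      run_pipeline(co, run_config(seed = 404), models = "rf",
                   explain_windows = 0)
    }
    list(a = run_once(), b = run_once())
  })
}

# acceptance-scale study run: 12 subjects, five 60 s stages, fixed master seed
acceptance_run <- function() {
  cached("acceptance_run", {
    co <- default_study_cohort(12, 60, seed = 42)
    run_pipeline(co, run_config(seed = 42), models = "rf",
                 explain_windows = 100)
  })
}
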