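# vo2gait

Two-stage estimation of oxygen uptake (VO2) from a single calf-mounted
inertial measurement unit (IMU), with subject-independent evaluation.

Continuous VO2 measurement normally requires breath-by-breath calorimetry.
`vo2gait` implements a wearable alternative for graded treadmill walking:

1. **Stage 1 — heel-strike (HS) detection.** Each 100 Hz IMU sample is
   described by 15 features (raw channels, accelerometer/gyroscope
   magnitudes `a(t) = sqrt(ax² + ay² + az²)`, their finite differences, and
   rolling statistics of `a(t)` over w = 5 samples). Classifiers: a
   150-tree random forest with balanced class weights `w_c = N/(2N_c)`; an
   extreme learning machine (ELM) with 150 fixed random tanh units whose
   output weights solve the least-squares problem in closed form
   (`beta = H⁺y` via SVD); their probability-mean ensemble; and a stacked
   ensemble whose XGBoost meta-learner consumes `z = [p_RF, p_ELM]` built
   from subject-grouped out-of-fold base predictions. Detections at
   `p >= tau = 0.5` are consolidated into one event per strike.
2. **Stage 2 — VO2 regression.** Non-overlapping 30 s windows yield 15
   kinematic/gait/spectral features (optionally +5 demographics), with the
   per-subject z-normalized VO2 of the *subsequent* 30 s as target.
   Models: a 700-tree random forest (depth 18, `d/3` features per split)
   and a stacked regressor (RF + XGBoost + ridge-regularized ELM bases,
   closed-form ridge meta-learner on standardized out-of-fold predictions).

Everything is scored by leave-one-subject-out (LOSO) cross-validation with
per-fold `R² = 1 − SS_res/SS_tot` (fold excluded when test-target variance
< 1e-4 or fewer than 3 windows), and stage 2 runs twice — once from
ground-truth HS annotations, once from stage-1 predictions — with paired
t / Wilcoxon / Cohen's d statistics on the per-fold difference. Exact
TreeSHAP attributions (C++ implementation, cross-checked against XGBoost's
native values) rank feature importance by mean |SHAP|.

A synthetic treadmill-gait + VO2 simulator (graded five-stage protocol,
impact-like HS transients at subject-specific cadence, stride-periodic
gyroscope oscillation, first-order VO2 on-kinetics with AR(1) breath noise)
makes the full pipeline testable without private subject data. See the
methods vignette (`vignettes/vo2gait-methods.Rmd`) for model details,
parameter choices and limitations.

## Worked example

```r
library(vo2gait)

cohort <- default_study_cohort(n_subjects = 12, stage_duration_s = 60, seed = 1)
res <- run_pipeline(cohort, run_config(seed = 1), models = "rf")

sapply(res$hs$aggregates, function(a) round(a$median, 3))
#>      elm ensemble       rf  stacked
#>    0.997    1.000    0.999    1.000

res$vo2$rf.gt
#> <LOSO VO2 report: rf, GT-HS>
#>   median R2 = 0.921, mean = 0.906 (sd 0.053), best = 0.971, worst = 0.765 over 12/12 folds

res$comparisons$rf$stats
#> <paired comparison GT-HS vs Pred-HS over 12 folds>
#>   delta median (Pred-HS - GT-HS): -0.0017
#>   paired t p = 0.263, Wilcoxon p = 0.4238, Cohen's d = -0.341, Shapiro p = 0.5936

head(res$shap$ranking, 3)
#>     feature mean_abs_shap
#> 1  gyro_std    0.21351888
#> 2  gyro_rms    0.19516499
#> 3 bandpower    0.04114298
```

Reading: the ELM+RF ensemble detects heel strikes with median event-level
F1 ≈ 1.0 on the synthetic cohort (±3-sample matching); the RF regressor
explains ~0.92 of the held-out subjects' normalized VO2 variance per median
fold; and swapping ground-truth for predicted heel strikes changes the
median R² by less than 0.01 with non-significant paired tests — the
pipeline's central claim. Gyroscope variability tops the importance ranking
on this cohort, where angular-velocity amplitude tracks belt speed.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/vo2pipe.R simulate --out data --subjects 12 --seed 1
Rscript inst/cli/vo2pipe.R stage1 --data data --out results
Rscript inst/cli/vo2pipe.R compare --data data --out results --model rf
```

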