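Package: vo2gait
Title: Two-Stage Heel-Strike Detection and Oxygen-Uptake Estimation from a Single IMU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stage pipeline for wearable gait analysis with a single
    calf-mounted inertial measurement unit (IMU): stage one detects heel-strike events
    from 100 Hz accelerometer and gyroscope streams using a random forest, a closed-form
    extreme learning machine (ELM), their probability-mean ensemble, and a stacked
    ensemble with an XGBoost meta-learner; stage two estimates per-subject normalized
    oxygen uptake (VO2) from 30-second window features (kinematic, gait-temporal, and
    Welch spectral descriptors, optionally with demographics) using random-forest and
    stacked ridge-meta regression. Evaluation is leave-one-subject-out with fold
    exclusion rules, paired statistics comparing ground-truth versus predicted
    heel-strike feature sources, and exact TreeSHAP attributions for the tree models.
    Ships a synthetic treadmill-gait and VO2 simulator so the full pipeline is testable
    without private subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    Rcpp,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
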