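---
title: "Methods: two-stage heel-strike detection and VO2 estimation from a single IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage heel-strike detection and VO2 estimation from a single IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Oxygen uptake (VO2) is the reference measure of exercise intensity, but
breath-by-breath calorimetry requires a mask and a metabolic cart. A single
calf-mounted inertial measurement unit (IMU) — a tri-axial accelerometer and
gyroscope sampled at 100 Hz — is a practical surrogate, provided two problems
are solved: detecting gait events (heel strikes, HS) automatically, and
mapping short windows of movement to a physiological target. `vo2gait`
implements both stages and, crucially, evaluates them *subject-independently*:
every model is scored under leave-one-subject-out (LOSO) cross-validation,
so no window or sample from a test subject ever reaches a fit.

The package's central scientific question is whether the second stage
degrades when its gait features come from *predicted* heel strikes rather
than manual annotations. The evaluation module answers it with paired
statistics over LOSO folds (paired t, Wilcoxon signed-rank, paired Cohen's
d, Shapiro-Wilk on the differences).

## Stage 1: heel-strike detection

Each IMU sample is described by a 15-dimensional vector: the six raw
channels; the accelerometer and gyroscope magnitudes
$a(t)=\sqrt{a_x^2+a_y^2+a_z^2}$, $\omega(t)$ likewise; their first-order
finite differences; and five rolling statistics of $a(t)$ (mean, population
standard deviation, max, min, range) over a centered window of $w = 5$
samples. Numerical choices at the edges: the derivative at the first sample
is set to 0 (it is undefined there, and this keeps $N$ rows aligned with
$N$ labels), and edge windows are truncated rather than padded, which
affects at most $(w-1)/2$ rows per side.

Four classifiers are trained on these features:

* **Random forest** — 150 trees, $\sqrt{d}$ candidate features per split,
  balanced class weights $w_c = N/(2N_c)$ (heel-strike samples are ~1% of
  the stream), out-of-bag error retained.
* **Extreme learning machine (ELM)** — a single hidden layer of 150 tanh
  units whose input weights and biases are drawn once from $U(-1,1)$ and
  never updated; only the output weights are learned, in closed form. With
  no penalty the minimum-norm least-squares solution is taken via the SVD
  pseudo-inverse — the normal-equations form $(H^TH)^{-1}H^Ty$ is
  algebraically equivalent where the inverse exists but numerically fragile,
  so the SVD route is used throughout. Two package-level choices make the
  ELM behave sensibly here: inputs are z-scored inside the model (raw
  gyroscope channels in deg/s would saturate the tanh), and classification
  targets are coded $\{-1,+1\}$ so that the logistic probability
  $\sigma(h^T\beta)$ crosses 0.5 exactly at the least-squares decision
  boundary. With $\{0,1\}$ coding and a heavily imbalanced stream, the
  fitted values sit above 0 almost everywhere and a 0.5 threshold on
  $\sigma(\cdot)$ would label nearly every sample positive.
* **ELM+RF ensemble** — the unweighted mean of the two class-1
  probabilities. No weighting is specified for this ensemble anywhere, so
  the symmetric rule is the defensible default.
* **Stacked ensemble** — the 2-dimensional meta-feature
  $z = [\hat p_{RF}, \hat p_{ELM}]$ feeds an XGBoost meta-learner
  (100 rounds, depth 3, learning rate 0.1 — these are package defaults, as
  no meta-learner configuration is published for this stage). Meta-features
  are **out-of-fold** base predictions from a subject-grouped internal
  5-fold split: in-sample base predictions would let the meta-learner
  exploit base-model overfit. The in-sample variant remains available
  behind `run_config(stage2 = list(oof_meta = FALSE))` for the regression
  stage, for comparison.

Probabilities become labels via $\hat y = 1$ iff $p \ge \tau^\*$ with
$\tau^\* = 0.5$. Because a true strike excites several adjacent samples,
maximal runs of positives are collapsed to their central sample, and events
closer than 30 samples (0.3 s, well below the shortest plausible stride)
are merged keeping the higher-probability event. The consolidated events —
one positive sample per detected strike — are written to the `hs_pred`
column, which keeps downstream event counts meaningful (a raw classifier
run of five samples would otherwise count as five steps).

Stage-1 scoring reports two granularities side by side, since the published
metric granularity is unstated: strict sample-level F1, and event-level F1
with greedy one-to-one matching within ±3 samples (30 ms). Event-level F1
is the headline.

A temporal convolutional network baseline is not included: it is an
optional component and no deep-learning framework is declared among the
package's dependencies.

## Stage 2: VO2 estimation

Recordings are segmented into non-overlapping 30 s windows (3000 samples;
trailing partial windows dropped). Per window, 15 features: magnitude
statistics (mean, population SD, RMS, range of $a$; population SD and RMS
of $\omega$), gait temporal features from the HS events in the window
(count $N_{HS}$, cadence $N_{HS}/T \times 60$, step frequency $N_{HS}/T$,
stride-interval mean and SD with divisor $N_{HS}-1$, both set to 0 when
fewer than two events occur — tree models need complete rows and 0 is a
recognizable "no gait" signature), jerk RMS over the $N_w - 1$ finite
differences, two Welch spectral features, and intensity defined as the
accelerometer RMS. Five demographics (age, height, weight, gender coded
M = 1 / F = 0, BMI) optionally extend the vector to $d = 20$.

Two definitions of "intensity" coexist in this problem domain: the window
feature f15 is the plain accelerometer RMS, while the composite
RMS × cadence product is a separate gait-summary quantity. The feature
vector uses the former; `composite_intensity()` exposes the latter but it
is never substituted into the model input.

The Welch estimator uses a periodic Hann taper, segment length 256, and 50%
overlap — the conventional default for this estimator; only taper and
segment length are prescribed, overlap is the package's choice. Dominant
frequency is searched over the full Nyquist range excluding the DC bin,
which is dominated by the gravity offset.

The target is the per-subject z-normalized VO2,
$(v - \mu_s)/(\sigma_s + 10^{-6})$, with $\mu_s, \sigma_s$ computed over the
subject's **entire** session. This is the faithful reading of the published
normalization even though it uses the test subject's own target statistics
inside LOSO; since the statistics are a monotone affine map, they do not
change within-subject ordering, but absolute-scale claims should not be
read into the predictions — the model captures relative within-subject
variation only. The target of the window covering $[t, t+30)$ is the mean
of the normalized breath samples in $[t+30, t+60)$: "the subsequent 30 s"
is ambiguous for breath-by-breath data, and averaging the following
interval is the stable choice. Windows with no breath sample in that
interval (always including the final window) are dropped.

Regressors:

* **RF** — 700 trees, depth 18, min leaf 2, $\lceil d/3\rceil$ features per
  split (the ceiling keeps $m \ge 1$ for any $d$).
* **Stacked** — base RF (300 trees, depth 6), base XGBoost (300 rounds,
  depth 4, $\eta = 0.05$, squared-error objective, subsample and column
  sampling at 1 since nothing else is specified), base ELM (250 hidden
  units, Tikhonov penalty $\alpha = 0.2$). Subject-grouped out-of-fold base
  predictions form $z = [\hat y_{RF}, \hat y_{XGB}, \hat y_{ELM}]$,
  standardized with training statistics; a closed-form ridge meta-learner
  ($\lambda = 1$ on the standardized meta-features, intercept unpenalized —
  a unit penalty is scale-appropriate after standardization and keeps the
  solve well-posed when the three bases collinearize) produces the final
  prediction.

## LOSO evaluation and fold exclusion

One fold per subject; the held-out subject contributes only test windows.
A per-fold $R^2 = 1 - SS_{res}/SS_{tot}$ uses the test-set mean and may be
negative. Folds with test-target variance below $10^{-4}$ or fewer than
three test windows are excluded from aggregates (the rule applies to the
VO2 task only; HS folds are always included). Aggregates report median,
mean, SD, best and worst; the median is the headline because a small
number of poorly-predicted subjects drags the mean far below the typical
fold.

For the GT-vs-Pred question, stage 2 runs twice per configuration with
identical windowing; only the gait temporal features can differ. The
comparison pairs per-fold $R^2$ over folds included under both sources
(intersecting with a warning if the sets disagree), reports
$\Delta = $ Pred − GT, and runs the paired tests. Cohen's d uses the
difference-score form mean(diff)/sd(diff); Wilcoxon drops zero differences
(the classic method) and uses the exact small-sample distribution when
applicable. Equivalence testing (TOST) is deliberately out of scope: a
non-significant difference is reported as exactly that.

## Explainability

Attributions for the tree regressors use exact path-dependent TreeSHAP
(implemented in C++): conditional expectations follow each tree's own
training-cover counts, so no background dataset must be chosen, and local
accuracy — base value plus attribution sum equals the prediction — holds to
machine precision per window. The same implementation applied to parsed
XGBoost trees reproduces XGBoost's native TreeSHAP to float32 precision,
which the test suite uses as an independent cross-check. Global importance
is the mean absolute attribution, ties broken alphabetically; the
demographic share is the fraction of that mass on the five demographic
features. ELM and stacked meta-paths are not attributed (no tree
structure); the random-forest regressor is the model explained by default.

## The synthetic cohort: what it emulates and what it does not

The simulator generates the study conditions the pipeline assumes: a
five-stage graded treadmill protocol (2.7 to 6.0 km/h, incline 0 to 14%
carried as metadata), per-subject cadence drawn from a truncated normal
(mean 81, SD 12, clipped to 55-112 steps/min) and scaled with the square
root of belt speed across stages; heel-strike transients (a 50 ms half-sine
of ~2 g plus a damped 10 Hz oscillation) on a 1 g gravity baseline with
3%-of-stride Gaussian step jitter truncated at ±10%; stride-periodic
gyroscope oscillation (~80 deg/s); additive Gaussian sensor noise
(0.05 g, 5 deg/s); and a VO2 signal following first-order on-kinetics
(time constant 30 s) toward a per-stage steady state that rises with an
analytic acceleration-RMS proxy and with cadence, sampled every 3 s with
AR(1) breath noise (SD 0.8 mL/kg/min, coefficient 0.7). The 3 s breath
interval is a simulator choice standing in for an unspecified analyzer
cadence. Per-subject lognormal multipliers (SD 0.15) on impulse amplitude
and both VO2 gains make LOSO folds non-trivial. Demographics are sampled
uniformly in the published cohort ranges with a 10:14 male:female ratio.

The simulator deliberately omits: forward-dynamic biomechanics,
incline-specific gait changes, sensor bias and drift, asymmetric or
pathological gait, and any VO2 nonstationarity beyond first-order kinetics.
Passing tests on this cohort therefore demonstrate that the pipeline's
machinery recovers planted structure under realistic signal-to-noise — not
that the published accuracy figures transfer to real subjects.

## Problem sizes and reproducibility

The shipped test and acceptance runs use 12 subjects with 60 s protocol
stages (five minutes of walking per subject, nine scored windows each); the
simulator's own default remains the full 180 s stages. These sizes are the
package's desk-scale choice and are stated here so results are read at the
right scale. All randomness flows from one master seed through named
substreams (`derive_seed()`), tree learners run single-threaded in tests,
and a repeated run with the same manifest reproduces byte-identical report
CSVs; fixed-precision serialization makes that byte-equality meaningful.

## Known limitations

Normalized VO2 only (no absolute mL/kg/min predictions); per-subject
normalization uses whole-session statistics (see above); the stage-1
training stream is subsampled per fold (all positive samples plus a seeded
negative subsample, capped at 15 000 rows) to keep forest training at desk
scale; no hyperparameter search anywhere — published values are taken as
given and package-chosen defaults are documented above.
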