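---
title: "Methods: calibrated core-temperature prediction with heatscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated core-temperature prediction with heatscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Core body temperature (CBT) is the physiological quantity that matters in
heat-strain management, but the gold-standard measurements (rectal,
esophageal, ingestible sensors) are invasive and impractical for continuous
occupational monitoring. Wearable-accessible signals — heart rate, chest
skin temperature, ambient conditions, work intensity, clothing insulation —
carry enough information to estimate CBT, but a point estimate alone is not
actionable in safety-critical settings: an alert policy needs to know *how
sure* the estimate is. `heatscope` implements a complete workflow for this
problem: a windowed hybrid sequence regressor, an output-stratified
inductive conformal calibration layer (SCOPE) that turns any regressor's
predictions into intervals with finite-sample coverage guarantees, an
extended-Kalman-filter (EKF) heart-rate benchmark, coverage-based
evaluation, session-level fine-tuning, and a four-state alert engine.

Because the operational cohorts this kind of model is trained on are
access-restricted, the package ships a synthetic multi-domain cohort
generator so that every stage — and every statistical claim — can be
exercised and tested end to end.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* of multi-domain
occupational heat-stress data, not the physiology of any individual. The
latent core temperature follows a first-order relaxation model on a
1-minute grid:

$$C_{t+1} = C_t + a\,w_t + b\,\mathrm{clo}_t\,\max(T^{amb}_t - 24,\,0)
  - c\,(C_t - 37) + \eta_t,$$

with work intensity $w_t$, clothing insulation in clo, ambient temperature
in °C, relaxation rate $c$ toward the 37 °C set point, and white process
noise $\eta_t$. This is the simplest mechanism that reproduces the
qualitative features the downstream layers care about: activity- and
heat-driven rise, exponential relaxation at rest, plateaus at a
condition-dependent equilibrium. Defaults are $a = 0.018$ °C/min per unit
work, $b = 0.0018$ °C/min per clo per °C of ambient excess over 24 °C, and
$c = 0.025$/min (a ~40-minute time constant). They were chosen once so that
a default cohort of 50+ subjects spans roughly 36.1–40.3 °C — the
physiological range reported for operational heat-stress cohorts — and were
not revisited afterwards.

Observed CBT adds heteroscedastic noise with standard deviation
$\sigma(C) = 0.1 + 0.2\,\max(C - 38, 0)$ °C: errors grow above a 38 °C
knee, which is the regime where uniform-width prediction intervals fail and
output-stratified calibration earns its keep. Heart rate is a subject
baseline plus linear work and thermal terms plus noise — so it can rise
independently of CBT, as it does in real data during exertion in the heat —
and skin temperature is a convex combination of core and ambient
temperature. Each of six domain labels (wildland fire, racing, mining,
nuclear, ordnance disposal, factory work) gets its own ambient and clothing
envelope; semi-sequential covariates change at most a configured number of
times per session. Missing values are injected independently per cell at
configurable per-column rates.

What the generator deliberately does **not** emulate: sensor-specific noise
signatures, motion artifacts, circadian drift, dehydration feedback, or any
individual thermoregulatory physiology. Passing tests on this generator
therefore demonstrates that the *pipeline machinery* (leakage-free
preprocessing, optimisation, conformal validity, alert logic) is correct —
not that the trained network would reach any particular accuracy on real
cohorts.

`oracle_predictor()` returns the observed CBT plus noise from a *known*
(possibly CBT-coupled) model. It exists so the conformal layer can be
validated against exact ground truth, independent of model training.

## Partitioning, scaling, imputation, windowing

Subject-level grouping is the non-negotiable constraint: all measurements
of one subject belong to exactly one of train / validation / calibration /
test. `carve_test_set()` reserves one whole domain (default the ordnance
disposal domain, the natural out-of-distribution probe) plus four random
subjects from every other domain for the test set. `group_split()` then
shuffles the remaining subjects with the seed and fills the
60:20:20 train/validation/calibration targets greedily by cumulative
measurement count, assigning each subject to the split with the largest
remaining deficit (ties resolved in train–validation–calibration order).
Achieved proportions are reported rather than forced: whole-subject
allocation cannot hit the targets exactly.

Scaling and imputation statistics come from training rows only.
`fit_scaler()` uses the population standard deviation (denominator $n$), and
replaces the sd of a constant column by 1 with a warning rather than
dividing by zero. `impute_knn()` fills each missing cell with the mean of
that feature over the $k$ (default 5; the literature leaves $k$ open)
nearest feature-complete *training* rows, with Euclidean distance computed
over the features observed in the query row; rows are never dropped, and a
row with no observed features at all falls back to training column means.

`make_windows()` cuts each session into overlapping windows: 30 minutes of
heart-rate and skin-temperature history ending at (and including) the
target minute, stride 1. Sessions shorter than the window are excluded, as
are windows whose end-time CBT is unobserved; a session of length $L$ thus
yields $L - W + 1$ windows at stride 1 when all targets are present. The
static vector carries the demographics (age, sex, mass, height, DuBois
body-surface area) plus the semi-sequential covariates at the window end
time; because those covariates change rarely within 30 minutes, the
end-time value is an adequate summary (a window-mean mode is available by
configuration). The CBT target is deliberately left in °C while the
features are standardised: every downstream quantity (RMSE, interval
half-widths, alert thresholds) then reads directly in °C.

## The hybrid regressor

The reference model is a hybrid of a bidirectional LSTM over the two
sequential channels and a dense ReLU encoder over the static vector, with
the two representations concatenated, dropout applied to the concatenation,
and a single linear output unit. The published hyperparameters are the
defaults: 3 LSTM units per direction, batch size 32, Adam at a fixed
learning rate of 0.001, at most 50 epochs, early stopping on validation
loss with patience 5, dropout 0.5, data shuffled before every epoch, and
the best-validation-epoch weights restored. Choices the literature leaves
open were fixed as follows: mean-squared-error loss (consistent with RMSE
reporting), a 16-unit single hidden layer in the static branch, dropout on
the concatenated vector (rather than inside the recurrence), and a plain
linear unit as the decision layer. The output bias is initialised at the
training-target mean so the untrained network predicts a sensible constant.

The implementation is written directly in vectorised base R — forward pass,
backpropagation through time, and Adam — and is verified against numerical
differentiation in the test suite (agreement to ~1e-9 on every parameter).
At the default problem size (a few thousand windows of length 30) training
runs in seconds on one CPU; inference is deterministic because dropout is
disabled at prediction time. A window-mean linear baseline (`cbt_baseline()`)
implements the same fit/predict interface for fast tests and for pipelines
that do not need the network: the conformal layer is model-agnostic by
construction.

## SCOPE: output-stratified conformal calibration

Split (inductive) conformal prediction takes a held-out calibration set of
nonconformity scores $\epsilon_i = |\hat y_i - y_i|$ and, for confidence
level $\gamma$, returns the interval $\hat y \pm Q_\gamma$, where
$Q_\gamma$ is an upper quantile of the calibration scores. Under
exchangeability of calibration and test data the observed value falls
inside with probability at least $\gamma$ — regardless of the model or the
error distribution. A single global quantile, however, wastes width where
the model is accurate and under-covers locally where it is not.

SCOPE stratifies the calibration set by *predicted value*: the prediction
axis is cut into $n = \lceil N / D \rceil$ equal-frequency bins (interior
edges at the $i/n$ order-statistic quantiles of the calibration
predictions; target density $D = 1000$ points per stratum, so 23,862
calibration points give 24 strata), and quantiles are computed per stratum.
A new prediction is assigned to its stratum — half-open bins, last bin
closed, out-of-range predictions clamped to the extreme strata — and gets
that stratum's half-width. Stratifying on $\hat y$ rather than on input
features keeps the bins balanced by construction and captures exactly the
error-vs-predicted-value structure that heteroscedastic CBT noise creates.

Two quantile conventions are provided. The default is the finite-sample
conformal order statistic $k = \lceil \gamma (m + 1) \rceil$ (clamped to
$m$), which preserves the marginal coverage guarantee; a plain empirical
quantile $k = \lceil \gamma m \rceil$ is available for comparison, since
published descriptions of quantile choice are often silent on the
convention. Sorted scores are retained in the fitted table so any level not
on the precomputed grid is recomputed exactly on demand, and so the
serialised JSON document reconstructs the calibrator bit-for-bit. When
$N < 2D$ the fit falls back to a single stratum — plain inductive conformal
prediction — with a warning, rather than estimating tail quantiles from
half-filled bins.

Numerical conventions worth stating: ties in predicted values may unbalance
stratum counts (counts are reported, not forced); intervals are symmetric
about $\hat y$ by construction; interval width is non-decreasing in the
level within every stratum because order statistics are.

## The EKF benchmark

The comparison method is a scalar-state extended Kalman filter estimating
CBT from heart rate alone: random-walk time update
($CT^- = CT$, $P^- = P + q$), observation through a mapping $m(CT)$
linearised at the prior, gain $K = P^- H / (H^2 P^- + r)$, and the usual
measurement update. Defaults follow the published quadratic mapping
$m(CT) = -7887.1 + 384.4286\,CT - 4.5714\,CT^2$ with process variance
$q = 0.000484$ °C²/min and observation variance $r = 356.4458$ bpm², and
the standard initialisation at 37.1 °C with variance 0.01 °C²; a sigmoid
mapping family is available but not tuned. Minutes with missing heart rate
receive the time update only. The filter's standard deviation
$\sqrt{P}$ is its uncertainty measure; since the filter is Gaussian by
assumption, comparison intervals are $CT \pm z(\gamma)\sqrt{P}$ — unlike
SCOPE's, these carry no distribution-free guarantee, which is precisely the
contrast the evaluation layer quantifies. The first 30 minutes of every run
are flagged as burn-in and excluded from evaluation, the period over which
initialisation effects decay.

One design note on testing initialisation-independence: the published
initial variance of 0.01 °C² asserts near-certainty in the 37.1 °C starting
state. When a run is *deliberately* started at a wrong value (the package's
convergence experiments use 36.5 and 38.0 °C), that certainty is
contradictory — at the default noise settings the linearised contraction
rate is only ~0.95/min, so a 1.5 °C initial spread would survive well past
30 minutes. The experiments therefore pair the wrong starting values with
an initial variance of 1.0 °C², telling the filter the truth about its own
ignorance; it then converges to within 0.05 °C well inside the 30-minute
burn-in, reproducing the published behaviour.

## Evaluation, fine-tuning, alerts

RMSE is reported at three levels: dataset split, domain, and
subject-session, with sessions below 10 valid timepoints (both prediction
and observation present) excluded. Paired model comparisons use the
two-sided Wilcoxon signed-rank test with zeros discarded; the exact
signed-rank null is used for 25 or fewer untied pairs and the
tie-corrected normal approximation otherwise (the implementation is checked
against exhaustive sign-assignment enumeration and against `wilcox.test`).
Coverage is the percentage of observations inside their intervals, bounds
inclusive (a measure-zero convention for continuous data). The coverage
curve evaluates coverage on a 1–99% confidence grid, and its area (AUC) is
the trapezoidal integral over 0–100 — anchored at the conformal limits
(0, 0) and (100, 100), so perfect calibration integrates to exactly 5000, a
constant-100% curve to 10000, and percent-reduction comparisons are rounded
half-even to one decimal.

Fine-tuning addresses a subtlety of marginal guarantees: coverage holds *on
average* over the calibration distribution, not for every subject or
session. `session_coverage_curve()` computes the realised coverage of the
globally calibrated intervals on one local dataset across the level grid,
and `calibrate_level()` finds the smallest nominal level whose realised
local coverage reaches the target — by linear interpolation on the
running-maximum (monotone-ized) curve, since empirical curves on small
sessions are noisy and need not be monotone. Sessions the model predicts
unusually well calibrate to far lower nominal levels (hence narrower
intervals at the same realised coverage); if the curve never reaches the
target, the maximum level is returned flagged unreachable rather than
extrapolated. Local sets below 10 points are refused — the session filter
reused.

The alert engine classifies intervals against a configurable band ladder
(defaults: Nominal 36.5–37.75 °C; Advisory 36–36.5 and 37.75–38; Caution
35–36 and 38–38.9; Warning below 35 or above 38.9; each band closed at its
lower edge so touching endpoints are owned uniquely). The default
adverse-bound policy judges the upper bound against the hot-side bands and
the lower bound against the cold-side bands and takes the more severe
state — so enlarging an interval can never reduce severity, and a
zero-width interval reduces to point classification. "Sustained trend"
behaviour is a run-length persistence filter: escalation requires the raw
classification to hold for a configured number of consecutive minutes
(default 1, i.e. off), de-escalation is immediate, which is the
conservative direction for safety alerts.

## Problem sizes and reproducibility

The package's own experiments are sized for a desk run: the demonstration
pipeline (`demo_config()`) simulates ~72 subjects across six domains
(roughly 7,500 training and 2,400 calibration windows), trains the 3-unit
hybrid in well under a minute on one CPU, and completes end to end in tens
of seconds; the conformal-coverage experiments use 5,000 calibration and
20,000 evaluation points at density 1000. Every stochastic stage takes an
explicit seed, reruns with the same configuration reproduce splits, fitted
tables and serialised artifacts exactly, and `with_seed()` semantics leave
the caller's RNG stream untouched.

## Known limitations

The generator's thermoregulation is deliberately minimal; absolute RMSE
numbers on synthetic data say nothing about accuracy on real cohorts. The
EKF benchmark uses literature coefficients, not the proprietary tool it
stands in for, so cross-method gaps should be read qualitatively. SCOPE's
per-stratum coverage is approximate (the guarantee is marginal within the
calibration distribution); strata at the extremes of the prediction range
rely on clamping for out-of-range predictions; and exchangeability — the
load-bearing assumption — is genuinely violated when test subjects differ
systematically from calibration subjects, which is exactly when
session-level fine-tuning is the appropriate remedy.
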