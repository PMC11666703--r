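---
title: "Methods: pulse wave analysis, boosted regression and imbalance handling in ppgbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse wave analysis, boosted regression and imbalance handling in ppgbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cuff-based blood pressure (BP) measurement is episodic and uncomfortable;
the photoplethysmogram (PPG) — an optical record of blood-volume pulsation,
available from any pulse-oximeter or wearable — is continuous and cheap.
`ppgbp` implements a complete single-site, single-cycle pipeline from raw
PPG segments to systolic/diastolic pressure estimates (mmHg) and a
hypertension screen: preprocessing and quality gating, pulse-wave-analysis
(PWA) feature extraction, feature ranking, an AdaBoost.R2 ensemble
regressor, SMOTE/undersampling for the imbalanced classification task, and
an evaluation suite (MAE/STD, British Hypertension Society grading,
confusion metrics, ROC/AUC). A seeded synthetic study generator stands in
for clinical data so that every stage is exercised and tested without any
download.

## Signal model and preprocessing

A PPG segment is a short (default 2.1 s) amplitude series holding 2–3
beats. The cardiac content lives between the fundamental (~1–1.5 Hz) and
its first few harmonics, so preprocessing applies a **6th-order Butterworth
band-pass over 0.5–5 Hz**. Filtering is **zero-phase** (forward–backward,
`signal::filtfilt`): fiducial *timings* are the features of interest and a
causal filter would lag-shift them. After filtering, each segment is
**min–max normalized to [0, 1]**. (A verbal specification of "unit variance
on a scale from zero to one" is self-contradictory — unit variance and a
[0, 1] range cannot hold simultaneously — so the range convention, which
the feature definitions rely on, is the one implemented.)

Segment quality is scored by the skewness signal quality index (S-SQI):
the Fisher–Pearson coefficient

$$ g = \frac{\sum_{i=1}^{n} (T_i - \bar T)^3}{n s^3}, $$

with $s$ the population standard deviation of the samples. Clean pulses are
right-skewed (narrow systolic peaks over a broad diastolic baseline);
symmetric noise scores near zero. The gate keeps segments with
`sqi >= threshold` *and* at least one complete detected cycle. No universal
threshold exists; the default is 0 (keeps all pulse-like segments) and the
value is exposed everywhere. S-SQI is computed on the filtered, normalized
segment; computing it pre-filter mostly measures baseline wander.

Cycle segmentation finds systolic peaks as prominence-gated local maxima
(defaults: prominence at least 0.2 of the amplitude range, separation at
least 0.4 s — a 150 bpm ceiling) and takes the minima between successive
peaks as pulse feet. The stretch before the first peak contributes its
minimum too (it is the true foot whether the segment starts at onset or
mid-fall). The final peak's cycle has no closing foot inside the segment
and is dropped as incomplete. All constants are plumbing defaults and
overridable.

## The feature set

One complete foot-to-foot cycle per segment is analysed (single-cycle PWA).
Fiducial points: foot (cycle start), maximum-slope point (argmax of the
first difference before the systolic peak), systolic peak (global maximum,
required in the first 60% of the cycle), diastolic peak (most prominent
local maximum after the systolic peak). When the reflected wave is only a
shoulder, the inflection point — minimum absolute second difference after
the peak — is used and flagged; this is common PWA practice.

The registry holds **46 signal features + 5 demographics** (age, height,
weight, gender, BMI):

* *Basic*: period, mean, STD, RMS, maximum slope (time and value),
  systolic/diastolic sub-periods, diastolic peak time and value, Fisher
  skewness. Index-type features are emitted in **seconds from the foot**,
  not raw sample indices, so every feature is sampling-rate invariant.
* *Widths*: systolic-side (SW) and diastolic-side (DW) widths at 25/50/75%
  of pulse height, plus their ratios; crossings located by linear
  interpolation between samples.
* *Amplitude*: LASI (systolic→diastolic peak delay in seconds, a large
  artery stiffness surrogate — the plain time-difference convention) and
  augmentation (diastolic/systolic peak amplitude ratio).
* *Areas*: trapezoidal areas s1–s4 under the pulse partitioned at the
  max-slope point, systolic peak and diastolic peak; they sum exactly to
  the total cycle area (shared boundary ordinates).
* *Wavelet*: max/min/mean/std of the approximation (cA4) and detail
  (cD1–cD4) coefficients of a 4-level discrete wavelet transform
  (Daubechies db4 by default).

Some published feature lists for this pipeline quote a count of 48; the
enumerable registry here yields 46 signal features, and the count is
derived from the registry rather than hard-coded, so the table of record
is `feature_registry()`.

### DWT conventions

Stated band edges for the five coefficient vectors (cD1 = 2.5–5 Hz, … ,
cA4 = 0–0.3125 Hz) imply a 10 Hz effective sampling rate, at which a
single ~0.8 s cycle would hold ~8 samples — too short for a 4-level
transform. `ppgbp` therefore resamples each cycle to a fixed dyadic length
(128 samples) before the transform: coefficient vectors get stable lengths,
the statistics become sampling-rate invariant, and the per-level octave
structure is preserved relative to the beat. A native-rate mode
(`n_resample = NA`) exists for signals that already satisfy the length
constraints. The transform uses **periodized (circular) extension**, making
it exactly orthogonal: coefficient energies sum to the signal energy to
machine precision, which the tests assert at 1e-6 relative tolerance.
Symmetric padding was considered and rejected because it produces redundant
coefficients and breaks exact energy conservation.

## Feature selection

Pearson correlations screen near-duplicate features: within any pair with
|r| above 0.9 ("strongly correlated"; the threshold is a configurable
judgment call), the lower-importance member is dropped. Importance comes
from a single decision tree: for every internal node $t$ splitting on a
feature,

$$ \mathrm{importance} \mathrel{+}= \frac{N_t}{N}\left(G -
   \frac{N_{t,R}}{N_t} G_R - \frac{N_{t,L}}{N_t} G_L \right), $$

with $G$ the Gini impurity for classification and the variance for
regression (its standard regression analogue), normalized to sum to 1. The
tree inducer is implemented in-package (exhaustive split search, minimum
leaf 3, unrestricted depth, deterministic tie-breaking by column order) so
that every node's statistics are recorded and the sum is auditable against
a brute-force oracle; `rpart` serves as an independent cross-check in the
tests. Curated presets (`feature_preset()`) capture the subsets this
pipeline typically settles on for SBP, DBP and the hypertension task.

## AdaBoost.R2 regression

The regressor is Drucker-style AdaBoost.R2 with a pluggable base learner.
Per round $t$: fit a base learner on a weighted bootstrap resample drawn
from the sample distribution $D_t$; compute absolute errors on the full
training set and normalize by the maximum,
$L_i = |\hat y_i - y_i| / \max_j |\hat y_j - y_j|$ (the default *linear*
loss; square and exponential variants are selectable — the linear form is
the classical default where none is stated); form the weighted average
loss $\bar L = \sum_i D_t(i) L_i$. If $\bar L \ge 0.5$ the round is
rejected and boosting stops; otherwise $\beta_t = \bar L / (1 - \bar L)
\in (0, 1)$ and

$$ D_{t+1}(i) = \frac{D_t(i)\, \beta_t^{\,\mathrm{lr}\,(1 - L_i)}}{Z_t}, $$

with $Z_t$ normalizing to a distribution. The learning rate
(default 0.1) enters as an exponent multiplier in the update and as a
factor on the prediction weights — the dominant convention in published
implementations. Prediction is the **weighted median** of the learners'
outputs with weights $\mathrm{lr}\cdot\log(1/\beta_t)$: sort the
predictions and return the first whose cumulative weight reaches half the
total. The round cap (default 300) counts *attempted* rounds; a perfect
fit is stored with near-total confidence and stops the loop.

Weighted-bootstrap fitting is the default because it works for any base
learner; weight pass-through (`resample = FALSE`) is available for
learners with native weight support. The default base learner is
leaf-wise gradient-boosted trees (xgboost, `grow_policy = "lossguide"`)
configured with 31 leaves, unlimited depth, learning rate 0.01, L1
regularization 0.1, minimum child weight 3, row/column subsampling
0.9/0.7 and 2000 trees; an `rpart` tree base reproduces the classical
tree-boosting comparator, and building a gradient-boosting engine is
deliberately out of scope — the contract isolates it.

## Imbalance handling and classification

Hypertension is labelled by the strict clinical rule SBP > 130 mmHg *or*
DBP > 80 mmHg (boundary values negative). At ~20% prevalence the task is
moderately imbalanced; two remedies are provided. *Undersampling* randomly
removes majority rows until the classes match. *SMOTE* synthesizes
minority points: for each minority sample $x$, find its $k$ nearest
minority neighbours by Euclidean distance (ties broken by stable row
order), then generate $x_{new} = x + \mathrm{rand}(0,1)\,(x_n - x)$ with a
fresh uniform draw per sample, cycling over minority points until the
classes balance exactly; originals are never altered. Distances use
unscaled features by default (a standardize flag exists) — with the
pipeline's feature set the dominant scales are comparable, and the
unscaled convention keeps the geometry interpretable. Small $k$ respects
local structure; large $k$ can link distant minority clusters and generate
implausible interpolants, a geometric property the tests demonstrate on a
two-cluster fixture. Rebalancing is applied **strictly to the training
portion** after the split, so no synthetic point (or dropped row) leaks
into evaluation; a pipeline that rebalanced before splitting would report
optimistic metrics. The classifier is a random forest at package defaults
(forests need no tuning to be competitive here, keeping the comparison
about the rebalancing method).

## Evaluation

Regression: MAE of predictions and the sample standard deviation
(divisor $n-1$) of the absolute errors. (A printed formula for the latter
that omits the square on the deviations is treated as a typo; the
implemented quantity is the standard SD of absolute errors, which actually
measures their dispersion.) BHS grading computes the cumulative
percentages of absolute errors within 5/10/15 mmHg; grade A requires
60/85/95, B 50/75/90, C 40/65/85, all three thresholds at once, else D.
Classification: confusion counts, sensitivity/specificity/precision/
recall/F1 (zero-denominator metrics reported as `NA`, not errors), and a
threshold-sweep ROC with trapezoidal AUC — algebraically equal to the
pairwise probability $P(s^+ > s^-) + \tfrac12 P(\text{tie})$, which the
tests verify by brute force. The split harness holds out 20% of rows,
5-fold cross-validates the rest, and averages the five models' test-set
predictions.

One caveat the package inherits from segment-level splitting: with several
segments per subject, a subject can appear on both sides of the split, so
demographic features act as a subject fingerprint and inflate apparent
accuracy. The tests that compare morphology against demographics therefore
use one segment per subject; analyses that need subject-level claims
should do the same.

## The synthetic study generator

`synth_config()` defines the simulated study. Demographics are truncated
normals matching a published cohort's moments (age 57.42 ± 15.98 y, height
161.44 ± 8.82 cm, BMI 22.83 ± 3.93 kg/m², heart rate 74.94 ± 10.24 bpm,
53.55% male; truncation bounds age 18–100, height 120–210 keep values
physiological); weight is derived from BMI and height so the BMI identity
holds exactly. SBP/DBP follow a linear model in age and BMI with
correlated residuals whose marginal SDs match the cohort (20.64 / 11.30
mmHg); the intercepts are calibrated by an internal fixed-seed Monte Carlo
root-find so that the configured hypertension prevalence (default 19.67%)
is met in expectation. Those cohort BP means are themselves inconsistent
with a ~20% prevalence under the strict >130/>80 rule, and the generator
resolves the conflict in favour of the prevalence, which the imbalance
machinery depends on.

Each pulse is a **sum of two Gaussians** — systolic wave plus reflected
diastolic wave — repeated at the cardiac period (60/heart-rate seconds).
This kernel was chosen because every time-domain feature above (peaks,
slopes, widths, areas) is analytically computable from it. BP enters
through a monotone mapping: higher SBP shortens the systolic→diastolic
delay (delay fraction 0.36 − 0.0012·(SBP − 128.75), clamped to
[0.27, 0.45] of the period so the inter-beat trough always stays deeper
than the inter-wave notch) and raises the augmentation ratio
(0.38 + 0.004·(SBP − 128.75), clamped to [0.10, 0.80]); higher DBP widens
the diastolic wave (width fraction 0.090 + 0.002·(DBP − 71.73), clamped to
[0.05, 0.18]). Gaussian jitter (SD 0.02 on the delay and augmentation) is
added unless disabled. Segments are phased to start at a pulse foot and
carry a ~0.2 Hz baseline-wander sinusoid (amplitude 0.05) and white noise
(SD 0.02); the analytic ground-truth fiducial times ride along for
round-trip tests. Default sampling rate is 125 Hz — every downstream
computation is rate-agnostic, and the tests include an invariance check —
with 2.1 s segments.

What this emulates: plausible BP-linked single-cycle morphology,
demographically realistic cohorts, controllable noise, exact ground truth.
What it does not: real pulse shape classes (age-dependent notch
morphologies), motion artifacts, sensor/LED physics, or any claim that the
chosen monotone morphology–BP mapping is physiologic. Passing tests show
the pipeline recovers structure that is present; they do not certify
clinical accuracy, which is why published database error values are not
used as reproduction targets here.

## Problem sizes and numerics

The test suite works at reduced scale (cohorts of 40–120 subjects, tree
base learners, tens of boosting rounds) — chosen so the full suite runs in
about a minute while every statistical check retains power; the
calibration checks use 5000 subjects and 3-standard-error bands. The
end-to-end script runs the study-scale configuration (219 subjects × 3
segments, gradient-boosted base learners, 300 trees × 12 rounds). Numeric
edge cases are handled explicitly: constant segments are rejected by
normalization and skewness with clear errors; cycles missing a
width-crossing yield `NA` features and a cycle is rejected above 20%
missingness; degenerate boosting rounds (perfect fit, or average loss ≥
0.5 on the first round) keep the model usable and are logged.

## Worked example

```{r, eval = FALSE}
library(ppgbp)

run <- run_pipeline(pipeline_config(
  synth = synth_config(seed = 1, n_subjects = 60),
  base = "tree", rounds = 8))
glance(run)
autoplot(run$regression$sbp$cv)
autoplot(run$classification$roc)
```

## Known limitations

* The morphology–BP link is a synthetic stand-in; absolute error levels on
  generator data say nothing about clinical performance.
* Only single-channel, single-cycle analysis: no beat averaging, no
  second-derivative (APG) features, no multi-sensor timing (PAT/PTT).
* The segment-level split caveat above.
* SMOTE distances are unscaled by default; standardize when mixing features
  of very different magnitudes.
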