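# ppgbp

Cuffless blood-pressure estimation from single-cycle pulse wave analysis
of the photoplethysmogram (PPG), for researchers in physiological signal
processing and wearable health who want a complete, testable, end-to-end
reference pipeline in R.

A PPG segment (2–3 beats) is band-pass filtered (Butterworth, order 6,
0.5–5 Hz, zero-phase), min–max normalized, quality-gated by the skewness
signal quality index

```
g = Σ (Tᵢ − T̄)³ / (n s³)
```

and split into foot-to-foot pulse cycles. One cycle yields 46
morphological features — fiducial timings, fractional pulse widths
(SW/DW at 25/50/75% height), LASI (systolic→diastolic peak delay),
augmentation ratio, inflection-point areas s1–s4, and max/min/mean/std of
4-level discrete-wavelet coefficients (cA4, cD1–cD4) — joined with five
demographics (age, height, weight, gender, BMI). Features are ranked by
decision-tree Gini importance,

```
importance += (N_t / N) · (G − N_tR/N_t · G_R − N_tL/N_t · G_L)
```

with correlation screening (|r| > 0.9 drops the weaker feature). SBP and
DBP are regressed by an AdaBoost.R2 ensemble over a pluggable base
learner (leaf-wise gradient-boosted trees by default): per round, sample
weights follow

```
D_{t+1}(i) = D_t(i) · β^(lr·(1−L_i)) / Z_t ,   β = L̄ / (1 − L̄)
```

with normalized per-sample losses L, rounds rejected when L̄ ≥ 0.5, and
prediction by the weighted median with weights `lr·log(1/β)`. For
hypertension screening (SBP > 130 or DBP > 80 mmHg), the imbalanced
training set is rebalanced by random undersampling or SMOTE
(`x_new = x + rand(0,1)·(x_n − x)` over k nearest minority neighbours)
before a random-forest classifier. Evaluation covers MAE and the SD of
absolute errors, British Hypertension Society grading (cumulative % of
errors within 5/10/15 mmHg → grade A–D), confusion metrics and ROC/AUC,
through a seeded 80/20 split with 5-fold cross-validated prediction
averaging.

A built-in synthetic study generator (two-Gaussian pulses whose
morphology is monotonically linked to BP, demographically calibrated
cohorts, analytic ground-truth fiducials) drives all tests and examples —
no external database needed.

## Tests

```r
testthat::test_dir("tests/testthat", package = "ppgbp",
                   load_package = "installed")
```

## Worked example

```r
library(ppgbp)

run <- run_pipeline(pipeline_config(
  synth = synth_config(seed = 1, n_subjects = 60),
  base = "tree", rounds = 8))
glance(run)
#> # A tibble: 1 × 9
#>   n_feature_rows sbp_mae sbp_std sbp_bhs dbp_mae dbp_std dbp_bhs htn_f1 htn_auc
#>            <int>   <dbl>   <dbl> <chr>     <dbl>   <dbl> <chr>    <dbl>   <dbl>
#> 1            180    11.5    8.42 D          4.13    4.48 B        0.947   0.996

tidy(run)
#> # A tibble: 2 × 7
#>   target   mae   std pct_within_5 pct_within_10 pct_within_15 grade
#>   <chr>  <dbl> <dbl>        <dbl>         <dbl>         <dbl> <chr>
#> 1 sbp    11.5   8.42         33.3          47.2          61.1 D
#> 2 dbp     4.13  4.48         72.2          88.9          94.4 B
```

Reading: 60 synthetic subjects × 3 segments gave 180 feature rows; on the
held-out 20%, SBP is predicted with 11.5 mmHg mean absolute error (BHS
grade D at this small scale and fast tree base), DBP with 4.13 mmHg
(grade B: 72% of errors within 5 mmHg, 89% within 10, 94% within 15), and
the SMOTE-rebalanced random forest screens hypertension with F1 0.95 and
AUC 0.996 on this synthetic cohort. `autoplot()` methods exist for
segments, cycles, ROC curves and cross-validated predictions;
`plot_importance()` and `plot_correlation()` cover feature selection.

A thin command-line wrapper with per-stage subcommands (`synth`,
`preprocess`, `extract`, `select`, `rebalance`, `train-bp`,
`classify-htn`, `evaluate`, `run`) is installed at
`system.file("cli/ppgbp.R", package = "ppgbp")`.

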