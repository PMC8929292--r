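---
title: "Methods: brain-age gap estimation and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-age gap estimation and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagtraj)
```

## The model

`bagtraj` treats brain-age estimation as penalized linear regression on
a fixed regional feature space. Each subject contributes a
1,430-dimensional vector: GMV and WMV over 246 gray-matter regions,
ALFF/ReHo/DC over the same 246 regions, and FA/MD/AD/RD over 50
white-matter regions, named `<modality>:<index>:<region>` in a fixed
canonical order so that weight vectors are comparable across runs.

The pipeline applied to a training set of controls is

1. per-feature gender residualization (OLS on the 0/1 gender code),
2. train-anchored z-scoring `Z = (x - u)/s`,
3. LASSO selection of age-related features,
4. an OLS regression head on the selected features.

Out-of-sample control brain age comes from leave-one-out
cross-validation; patients are scored by the model trained on all
controls. Raw predictions then receive the standard
regression-to-the-mean correction: `offset = alpha * CA + beta` is
fitted by OLS to the control gaps `BA - CA` and subtracted from every
prediction. Because the fitted residuals of an OLS line have mean zero,
the corrected control gap averages exactly zero — this is an algebraic
identity, not an empirical observation, and the test suite asserts it
to 1e-8.

The patient brain-age gap `BAG = correctedBA - CA` is regressed on CA
with polynomials of degree 1 and 2; the quadratic's stationary point
`-b/(2a)` (the vertex) defines the youth/middle split, `youth` iff
`CA < vertex`. With integer ages and a vertex of 47.33 this reproduces
bands ending at 47 and starting at 48.

### Assumptions

- Feature effects of age are smooth enough that a linear model on
  selected regional features captures them; no nonlinear regressors are
  offered by design.
- The gender confound acts additively and linearly per feature.
- Controls define normal aging: all normalization, selection,
  confound and bias parameters are estimated on controls only and
  applied unchanged to patients.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` (`bap_config`) | 0.3 | years per z-unit scale of the L1 penalty | LASSO penalty in the `1/(2n) RSS + lambda * ||w||_1` objective; `alpha_mode = "cv"` picks it by 10-fold CV instead |
| `loocv_mode` | `"nested"` | — | whether selection (and all other stages) refit inside every LOOCV fold (`nested`, leakage-free) or once on all rows (`single`) |
| `sd_type` | `"sample"` | — | SD convention of the z-score (n−1 denominator); population SD available |
| `degenerate` | `"drop"` | — | zero-variance features are dropped (or passed through as 0) |
| `rank_deficient` | `"error"` | — | rank-deficient OLS designs error by default; a pseudoinverse fallback handles exactly collinear selections |
| `bag_coeff_a`, `bag_vertex_c`, `bag_offset_d` (`cohort_config`) | 0.01, 47.33, 1 | yr/yr², yr, yr | patient BAG curve of the generator |
| `target_explained_var` | 0.85 | fraction | noise calibration of the generator (below) |

A fixed penalty is an unusual choice for a LASSO — cross-validation is
the standard — but a single fixed value makes the selected set a
deterministic function of the data and is therefore the default, with
`alpha_mode = "cv"` available. The value 0.3 assumes features are
z-scored and age is in years; it corresponds to admitting features
whose partial correlation with the age residual exceeds roughly
`0.3 / sd(residual)`.

### Selection placement

A single selection performed before LOOCV (`loocv_mode = "single"`)
produces one reportable selected-feature set, but the selection step
then sees every held-out label, which biases LOOCV accuracy
optimistically. The default is therefore `nested`: all stages refit per
fold. The single mode is retained because it is cheap (the
leave-one-out predictions of a fixed OLS head have the closed form
`y_i - e_i / (1 - h_ii)` via the hat matrix) and because the single
selected set is what one typically reports descriptively.

The same distinction matters for the permutation test. The test
shuffles age labels and re-runs the full pipeline per permutation, so
it is valid (the statistic is computed identically under the null) in
either mode. Its *power*, however, differs: in single mode the selection
leakage lets permuted-label models partially "fit" shuffled ages on a
wide independent feature space, shrinking the gap between observed and
permuted MAE. On synthetic cohorts with 1,430 mutually independent
columns this effect is maximal; real regional features are strongly
correlated (lower effective dimension), so the phenomenon is expected
to be milder on real data. The bundled acceptance script runs its
permutation quantity with the nested pipeline for this reason.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the analysis
assumes:

- ages uniform on [20, 60], rounded to whole years by default (matching
  integer age-band reporting); gender Bernoulli(0.5);
- control effective brain age equal to CA; patient effective age
  `CA + a (CA - c)^2 + d` with defaults a = 0.01 /yr, c = 47.33 yr,
  d = 1 yr — an upward-opening parabola whose elevated gap in youth
  declines toward the vertex;
- informative features `intercept + slope * effAge`
  (`+ curvature * effAge^2`) `+ gamma * gender + N(0, sigma)`, slopes
  of magnitude 0.5–1.5 per year with random signs, spread round-robin
  over the three modalities so every modality subset carries signal;
- the remaining columns are intercept plus noise.

Default cohort sizes are 205 controls and 138 patients, mirroring the
reference participant flow (154 and 209 recruited, 16 and 4 excluded
for head motion).

**Noise calibration.** When `noise_sd` is not given, it is set so that
the best linear read-out of age from the informative features leaves a
fixed fraction (default 15%) of the age variance unexplained: with
features `x_j = f_j(A) + e_j`, the optimal unbiased age estimate has
standard deviation `sigma / sqrt(sum_j f_j'(A)^2)`, and `sigma` is
solved from `sigma^2 / mean_i sum_j f_j'(age_i)^2 = 0.15 * Var(age)`.
The implied mean-absolute-error floor, `sqrt(2/pi)` times the average
optimal SD, is exposed as `noise_floor_mae()` and anchors the
parameter-recovery tests: the nested LOOCV of the calibrated cohort
(200 controls, 40 linear informative features among 1,430) must reach
r ≥ 0.8 with MAE within 1.5× that floor.

**What the generator does not emulate.** Real regional features are
strongly correlated within and across modalities, site/scanner effects
exist, age is not uniform, and feature noise is not homoscedastic
Gaussian. Passing tests therefore demonstrate that the pipeline
recovers known structure under its own assumptions — selection finds
planted signal, LOOCV accuracy approaches the information-theoretic
floor, the trajectory vertex is recovered — not that any particular
accuracy will be achieved on clinical data.

## Numerical choices

- LASSO is solved by coordinate descent (glmnet) at convergence
  threshold 1e-7 with a 1e5 iteration cap, along a 40-point
  log-spaced path from the data's critical penalty down to the target;
  this warm-started path is both faster and more stable than a
  single-penalty solve. A penalty at or above the critical value
  selects nothing (warning), and the regression head then predicts the
  training mean.
- Weight ranking is by |weight| descending with ties broken by
  canonical feature order, so rankings are deterministic.
- Zero-variance (degenerate) features are flagged at a 1e-12 SD
  threshold.
- Trajectory R² is computed directly from RSS/TSS with a TSS = 0 guard
  (a constant gap yields R² = 0 and negative adjusted R²), avoiding the
  0/0 artifact of the usual summary on exactly constant input.
- The quadratic/linear comparison uses adjusted R² as the primary
  criterion (AIC is reported); raw R² cannot decide between nested
  fits.
- The vertex is reported for either curvature sign — the analysis calls
  it a vertex, not a maximum — and the curvature sign is kept in the
  report so a "positive quadratic" claim is checkable.
- All randomness flows from explicit integer seeds; the same
  configuration and seed reproduce a byte-identical report
  (`write_study_report()` omits timestamps for this reason).

## Design choices that were genuinely open

- **Order of preprocessing.** Gender residualization precedes
  z-scoring. Residualization is scale-equivariant, so the order affects
  only scaling; fixing one order makes runs reproducible, and it is
  configurable via the exported stage functions.
- **Confound and normalization scope.** Both are fitted on training
  controls only and applied unchanged to patients, matching the
  train/test separation of the overall design.
- **Bias model inputs.** The correction is fitted on the controls'
  out-of-fold LOOCV predictions rather than refit (in-sample)
  predictions, avoiding optimism in `alpha`, `beta`.
- **Trajectory input.** The patient trajectory is fitted on
  bias-corrected BAG; fitting raw gaps would conflate the
  regression-to-the-mean slope with the clinical trajectory.
- **Band rule.** Strict `CA < vertex`. With integer ages this
  reproduces integer band edges (…47 | 48…) for a vertex of 47.33.
- **Permutation p-value.** Add-one smoothing,
  `(1 + #{MAE_perm <= MAE_obs}) / (1 + n_perm)`, so p is never zero.
- **t-test variant.** Welch by default (it reproduces the demographic
  desk checks from summary statistics); pooled available. Group
  comparisons of BA vs CA use two-sample tests even where pairing is
  available, for fidelity with the analysis design being implemented; a
  paired analysis would be more powerful.
- **Multiple testing.** None applied; reported p-values are labelled
  unadjusted.

## Problem sizes used by the bundled experiments

The test suite and acceptance script scale their simulations to desk
size as the package's own choice of experimental design: unit tests use
cohorts of 25–60 subjects with 20–90 features; the parameter-recovery
experiment uses 200 controls × 1,430 features (40 informative, 85%
explainable variance); the trajectory-recovery experiment uses 50
replicates of 150 patients with gap noise SD 2 yr; the null calibration
uses 200 replicates × 99 permutations on 60-subject, 20-column
pure-noise cohorts; the script's permutation quantity uses 99 nested
permutations on a 100-subject, 300-column cohort with the default
generative conditions.

## Limitations

- The estimator is multiple linear regression only; no GPR, random
  forests or deep models, and no spline/GAM trajectories.
- No site harmonization or nonlinear confound models.
- The synthetic generator's independence of feature noise makes
  selection harder (no redundancy to exploit) and permutation leakage
  stronger than on real, correlated data; absolute accuracies on real
  cohorts will differ.
- Cross-sectional only: a trajectory fitted across subjects is not a
  within-person aging curve.
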