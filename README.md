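# bagtraj

Brain-age gap estimation and aging-trajectory analysis from regional
multimodal MRI features.

## The problem

A brain-age model learns the mapping from neuroimaging features to
chronological age (CA) in healthy controls; applied to a clinical group,
the discrepancy between predicted brain age (BA) and CA — the brain-age
gap, BAG — indexes deviation from normal aging. In schizophrenia,
elevated BAG has been reported repeatedly, but whether the elevation is
uniform across the lifespan or concentrated in particular age ranges is
the interesting question: fitting the BAG-versus-CA relationship in
patients and locating the vertex of that trajectory lets one split a
cohort into age bands and test where BA and CA actually diverge.

`bagtraj` implements that entire analysis for subject-by-feature tables
derived from three MRI modalities — gray/white matter volume (GMV, WMV)
over a 246-region gray-matter parcellation, three resting-state
functional metrics (ALFF, ReHo, DC) over the same parcellation, and four
diffusion metrics (FA, MD, AD, RD) over a 50-region white-matter
parcellation — a 1,430-dimensional feature vector per subject.

## The method

For controls (NC) and patients (SZ):

1. **Confound removal** — each feature is residualized on gender by a
   linear model fitted on the training controls.
2. **Normalization** — train-anchored z-scoring, `Z = (x - u) / s` with
   `u`, `s` from the training subjects only.
3. **Feature selection** — LASSO regression of CA on the normalized
   features (penalty 0.3 by default, or chosen by cross-validation);
   features with nonzero coefficients are retained.
4. **Regression** — multiple linear regression (OLS) of CA on the
   selected features. Control BA is estimated by leave-one-out
   cross-validation (the whole pipeline refitted per fold by default);
   patients are predicted from the model trained on all controls.
5. **Bias correction** — the regression-to-the-mean age bias is removed
   by fitting `offset = alpha * CA + beta` to the control gaps and
   subtracting it everywhere: `correctedBA = BA - offset`. The mean
   corrected control BAG is exactly zero by construction.
6. **Trajectory** — linear and quadratic fits of patient BAG on CA are
   compared by adjusted R²; the quadratic vertex `-b/(2a)` splits all
   subjects into youth (`CA < vertex`) and middle-age bands.
7. **Inference** — permutation test of the LOOCV MAE (age labels
   shuffled, full pipeline re-run per permutation), band-wise
   two-sample t-tests of BA vs CA and of BAG between groups, chi-square
   and summary-statistic t-tests for demographics.

Because clinical feature tables are rarely shareable, the package ships
a synthetic cohort generator (`generate_cohort()`) producing tables
with the structure the analysis assumes — age-linear and age-quadratic
informative features, a gender confound, uninformative noise columns,
and a patient group whose effective brain age deviates from CA by a
positive quadratic BAG curve — together with the generating ground
truth, so every stage is testable end to end.

## Worked example

```r
library(bagtraj)

report <- run_full_study(study_config(seed = 1))
report
#> <study_report>
#>   cohort: 205 NC + 138 SZ, 1430 features (sMRI+fMRI+DTI)
#>   NC LOOCV: r = 0.885, MAE = 3.90 yr, R2 = 0.784, rMSE = 4.99 yr
#>   selected features: 110 (penalty 0.3)
#>   SZ BAG trajectory: quadratic a = 0.007762, vertex = 47.28 yr (preferred degree 2)
```

Reading the output: the control model predicts age to within ~3.9 years
(r = 0.885) from the multimodal features; 110 of the 1,430 features
survive selection; the patient BAG-versus-age relationship is better
described by an upward-opening parabola than a line, with its vertex
near 47 years — young patients carry an elevated gap that shrinks
toward midlife. Band-wise tests live in `report$group_tests`; e.g.
`report$group_tests$ba_vs_ca_SZ_youth$p_value` is ~0.004 for this seed
(young patients' BA significantly exceeds their CA), while the
corresponding control comparison is non-significant.

Individual stages are exposed as ordinary functions — for example:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
pred   <- loocv_predict(cohort$table[cohort$table$group == "NC", ],
                        bap_config())
accuracy(pred$ba, pred$age)
bias   <- fit_bias(pred$age, pred$ba)
```

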