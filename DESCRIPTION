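Package: bagtraj
Title: Brain-Age Gap Estimation and Aging-Trajectory Analysis from
    Multimodal MRI Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates brain age from regional multimodal MRI feature
    tables (structural, resting-state functional and diffusion metrics
    over standard gray- and white-matter parcellations) using
    LASSO-selected multiple linear regression with leave-one-out
    cross-validation in healthy controls, corrects the regression-to-
    the-mean age bias of the predictions, computes bias-corrected
    brain-age gaps, fits linear and quadratic gap-versus-age
    trajectories in a patient group, splits cohorts at the trajectory
    vertex, and runs the associated group comparisons and permutation
    significance tests. Includes a synthetic cohort generator so the
    full pipeline is testable without access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
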