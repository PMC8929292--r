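# Shared fixture builders. Everything is generated in code; no files.

# Feature table from a raw matrix; columns get valid canonical names.
make_table <- function(X, age, gender = NULL, group = "NC", ids = NULL) {
  n <- nrow(X)
  if (is.null(gender)) gender <- rep(c(0L, 1L), length.out = n)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  colnames(X) <- build_feature_names()[seq_len(ncol(X))]
  cbind(data.frame(subject_id = ids,
                   group = rep(group, length.out = n),
                   age = age, gender = gender,
                   stringsAsFactors = FALSE),
        as.data.frame(X, optional = TRUE))
}

# Small mixed-modality synthetic cohort for pipeline-level tests.
small_cohort_config <- function(seed = 1L, n_nc = 50L, n_sz = 40L,
                                n_lin = 12L, n_quad = 4L,
                                n_noise = 74L, ...) {
  cohort_config(n_nc = n_nc, n_sz = n_sz,
                n_informative_linear = n_lin,
                n_informative_quadratic = n_quad,
                n_noise = n_noise, seed = seed, ...)
}

# Cohort with no age signal at all (pure-noise features).
null_cohort_config <- function(seed, n = 60L, p = 20L) {
  cohort_config(n_nc = n, n_sz = 0L, n_informative_linear = 0L,
                n_informative_quadratic = 0L, n_noise = p,
                noise_sd = 1, seed = seed)
}

# The seeded recovery cohort used for parameter-recovery checks:
# n = 200 controls, full 1430-column layout, 40 linear informative
# features, noise calibrated so ~85% of age variance is explainable.
recovery_cohort_config <- function(seed = 101L) {
  cohort_config(n_nc = 200L, n_sz = 0L,
                n_informative_linear = 40L,
                n_informative_quadratic = 0L,
                n_noise = NULL,              # fill to 1430
                target_explained_var = 0.85,
                seed = seed)
}
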