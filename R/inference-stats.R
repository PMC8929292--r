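#' Permutation significance test of the LOOCV accuracy
#'
#' Shuffles the age labels of the training table `n_perm` times and
#' re-runs the full estimation pipeline — gender residualization,
#' normalization, feature selection and regression, all refitted on the
#' permuted labels — recording the LOOCV mean absolute error of each
#' permutation. The p-value uses add-one smoothing,
#' `p = (1 + #\{MAE_perm <= MAE_obs\}) / (1 + n_perm)`, so it is never
#' zero.
#'
#' @param nc_table Training (control) feature table.
#' @param config A [bap_config()] describing the pipeline to run; the
#'   observed and permuted statistics use the identical configuration.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the label shuffles.
#' @return An object of class `permutation_result`: `observed_mae`,
#'   `perm_mae` (length `n_perm`), `p_value`, `n_perm`, `seed`.
#' @export
permutation_test_mae <- function(nc_table, config = bap_config(),
                                 n_perm = 1000L, seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L)
    stop("`n_perm` must be a positive integer", call. = FALSE)
  obs <- loocv_predict(nc_table, config)
  observed_mae <- mean(abs(obs$ba - obs$age))
  set.seed(seed)
  perm_mae <- vapply(seq_len(n_perm), function(b) {
    shuffled <- nc_table
    shuffled$age <- sample(nc_table$age)
    pred <- tryCatch(loocv_predict(shuffled, config),
                     error = function(e)
                       stop("permutation ", b, ": ",
                            conditionMessage(e), call. = FALSE))
    mean(abs(pred$ba - pred$age))
  }, numeric(1L))
  structure(list(observed_mae = observed_mae, perm_mae = perm_mae,
                 p_value = (1 + sum(perm_mae <= observed_mae)) /
                   (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed MAE = %.2f yr vs %d permutations; p = %.4g\n",
    x$observed_mae, x$n_perm, x$p_value))
  invisible(x)
}

.group_test_result <- function(test, statistic, df, p_value,
                               groups = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 groups = groups),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$test, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-sample t-test
#'
#' Two-sided comparison of two independent samples; `variant = "welch"`
#' (default) does not assume equal variances, `"pooled"` does.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param variant `"welch"` or `"pooled"`.
#' @return A `group_test_result` with the statistic, degrees of
#'   freedom, p-value and per-group summaries.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(.group_test_result(paste0("two-sample t (", variant, ")"),
                                0, length(x) + length(y) - 2L, 1,
                                groups = .t_groups(x, y)))
    stop("two_sample_t: zero combined variance with unequal means",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  .group_test_result(paste0("two-sample t (", variant, ")"),
                     tt$statistic, tt$parameter, tt$p.value,
                     groups = .t_groups(x, y))
}

.t_groups <- function(x, y) {
  data.frame(group = c("x", "y"), n = c(length(x), length(y)),
             mean = c(mean(x), mean(y)),
             sd = c(stats::sd(x), stats::sd(y)))
}

#' Two-sample t-test from summary statistics
#'
#' Computes the t statistic and two-sided p-value directly from group
#' sizes, means and standard deviations — useful for desk-checking
#' printed demographic tables.
#'
#' @param n1,m1,sd1 Size, mean and SD of the first group.
#' @param n2,m2,sd2 Size, mean and SD of the second group.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A `group_test_result`.
#' @export
t_from_summary <- function(n1, m1, sd1, n2, m2, sd2,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2L || n2 < 2L)
    stop("t_from_summary needs n >= 2 per group", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0)
    stop("t_from_summary needs positive SDs", call. = FALSE)
  if (variant == "welch") {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    tstat <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  .group_test_result(paste0("two-sample t from summaries (", variant,
                            ")"),
                     tstat, df, 2 * stats::pt(-abs(tstat), df),
                     groups = data.frame(group = c("1", "2"),
                                         n = c(n1, n2),
                                         mean = c(m1, m2),
                                         sd = c(sd1, sd2)))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A `group_test_result` (df = 1).
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi_square_2x2: zero marginal", call. = FALSE)
  ct <- stats::chisq.test(counts, correct = correct)
  .group_test_result(paste0("chi-square (2x2",
                            if (correct) ", Yates-corrected", ")"),
                     ct$statistic, ct$parameter, ct$p.value,
                     groups = as.data.frame(as.table(counts)))
}
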