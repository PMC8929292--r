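#' Fit the age-bias correction model
#'
#' Regression-based brain-age predictions are biased toward the training
#' mean: young subjects are over-predicted and old subjects
#' under-predicted. The correction fits `offset = alpha * CA + beta` by
#' OLS of the raw gap `BA - CA` on `CA` over the control group, and
#' [apply_bias()] subtracts the fitted offset from every prediction
#' (controls and patients alike): `correctedBA = BA - offset`. By the
#' OLS residual property the mean corrected gap over the fitting cohort
#' is exactly zero.
#'
#' @param ca Chronological ages of the fitting (control) cohort.
#' @param ba Their raw predicted brain ages (normally out-of-fold LOOCV
#'   predictions).
#' @param ids Optional subject ids of the fitting cohort, kept for
#'   audit.
#' @return An object of class `bias_model` with `alpha` (slope) and
#'   `beta` (intercept, years).
#' @export
fit_bias <- function(ca, ba, ids = NULL) {
  stopifnot(length(ca) == length(ba), all(is.finite(ca)),
            all(is.finite(ba)))
  if (length(ca) < 3L)
    stop("fit_bias needs at least 3 control records", call. = FALSE)
  if (stats::var(ca) == 0)
    stop("fit_bias: chronological age has zero variance", call. = FALSE)
  cf <- stats::coef(stats::lm.fit(cbind(1, ca), ba - ca))
  structure(list(alpha = unname(cf[2L]), beta = unname(cf[1L]),
                 fit_ids = ids, n = length(ca)),
            class = "bias_model")
}

#' Apply the age-bias correction
#'
#' @param ba Raw predicted brain ages.
#' @param ca Chronological ages.
#' @param model A [fit_bias()] model.
#' @return Corrected brain ages `ba - (alpha * ca + beta)`.
#' @export
apply_bias <- function(ba, ca, model) {
  stopifnot(inherits(model, "bias_model"), length(ba) == length(ca))
  ba - (model$alpha * ca + model$beta)
}

#' Assemble per-subject prediction records
#'
#' Combines chronological age, raw and bias-corrected brain age, and
#' the brain-age gap `BAG = correctedBA - CA` into one record per
#' subject.
#'
#' @param subject_id,group,ca,ba_raw Per-subject vectors.
#' @param bias A [fit_bias()] model, or `NULL` to skip correction
#'   (corrected BA then equals raw BA).
#' @return A data.frame with columns `subject_id`, `group`, `ca`,
#'   `ba_raw`, `ba_corrected`, `bag`.
#' @export
prediction_records <- function(subject_id, group, ca, ba_raw,
                               bias = NULL) {
  ba_corrected <- if (is.null(bias)) ba_raw else
    apply_bias(ba_raw, ca, bias)
  data.frame(subject_id = as.character(subject_id), group = group,
             ca = ca, ba_raw = ba_raw, ba_corrected = ba_corrected,
             bag = ba_corrected - ca, stringsAsFactors = FALSE)
}

#' Fit a BAG-versus-age trajectory
#'
#' Polynomial OLS of the brain-age gap on chronological age, degree 1
#' (linear) or 2 (quadratic). For the quadratic fit the vertex age
#' `-b / (2a)` is reported; it is the stationary point of the fitted
#' parabola (a minimum of the gap when the curvature `a` is positive).
#'
#' @param ca Chronological ages.
#' @param bag Brain-age gaps (years).
#' @param degree 1 or 2.
#' @return An object of class `trajectory_fit`: `degree`,
#'   `coefficients` (intercept, linear, and for degree 2 quadratic
#'   term), `r2`, `adj_r2`, `aic`, `vertex` (degree 2 only), `n`.
#' @export
fit_trajectory <- function(ca, bag, degree = 2L) {
  degree <- as.integer(degree)
  stopifnot(degree %in% c(1L, 2L), length(ca) == length(bag),
            all(is.finite(ca)), all(is.finite(bag)))
  if (length(ca) <= degree + 1L)
    stop("fit_trajectory needs n > degree + 1", call. = FALSE)
  if (stats::var(ca) == 0)
    stop("fit_trajectory: degenerate design (all ages equal)",
         call. = FALSE)
  df <- data.frame(ca = ca, bag = bag)
  fit <- if (degree == 2L) stats::lm(bag ~ ca + I(ca^2), data = df)
         else stats::lm(bag ~ ca, data = df)
  cf <- stats::coef(fit)
  # R^2 computed directly; a zero total sum of squares (constant gap)
  # yields r2 = 0 rather than a 0/0 artifact
  n <- length(bag)
  tss <- sum((bag - mean(bag))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss <= 0) 0 else 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 1 - degree)
  vertex <- NULL
  if (degree == 2L) {
    a <- cf[["I(ca^2)"]]
    b <- cf[["ca"]]
    vertex <- if (a == 0) NA_real_ else -b / (2 * a)
  }
  structure(list(degree = degree,
                 coefficients = cf,
                 r2 = r2,
                 adj_r2 = adj_r2,
                 aic = stats::AIC(fit),
                 vertex = vertex,
                 n = length(ca)),
            class = "trajectory_fit")
}

#' Vertex age of a quadratic trajectory
#'
#' @param fit A degree-2 [fit_trajectory()] result.
#' @return The vertex age `-b / (2a)` in years.
#' @export
trajectory_vertex <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (fit$degree != 2L)
    stop("vertex is only defined for a quadratic trajectory",
         call. = FALSE)
  if (is.na(fit$vertex))
    stop("vertex undefined: quadratic coefficient is zero",
         call. = FALSE)
  fit$vertex
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> degree %d, n = %d: R2 = %.3f, adj R2 = %.3f, AIC = %.1f",
              x$degree, x$n, x$r2, x$adj_r2, x$aic))
  if (x$degree == 2L && !is.na(x$vertex))
    cat(sprintf(", vertex = %.2f yr", x$vertex))
  cat("\n")
  invisible(x)
}

#' Compare two trajectory fits
#'
#' Prefers the fit with the larger adjusted R-squared (primary
#' criterion); AIC is reported alongside. For nested polynomial fits on
#' the same data the raw R-squared of the higher degree is never below
#' the lower's, which is why the adjusted version is used.
#'
#' @param fit1,fit2 [fit_trajectory()] results on the same data.
#' @return A list: `preferred` (the winning fit), `criterion`,
#'   `table` (degree, r2, adj_r2, aic per candidate).
#' @export
compare_trajectories <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "trajectory_fit"),
            inherits(fit2, "trajectory_fit"))
  tab <- data.frame(degree = c(fit1$degree, fit2$degree),
                    r2 = c(fit1$r2, fit2$r2),
                    adj_r2 = c(fit1$adj_r2, fit2$adj_r2),
                    aic = c(fit1$aic, fit2$aic))
  preferred <- if (fit2$adj_r2 > fit1$adj_r2) fit2 else fit1
  list(preferred = preferred, criterion = "adj_r2", table = tab)
}

#' Split records into youth / middle-age bands at the trajectory vertex
#'
#' Subjects with chronological age strictly below the vertex are
#' labelled `youth`, all others `middle`. A vertex outside the observed
#' age range is allowed but flagged with a warning.
#'
#' @param records A data.frame with a `ca` column (e.g. from
#'   [prediction_records()]).
#' @param vertex Vertex age in years (finite).
#' @return `records` with an added `age_band` column (factor with
#'   levels `youth`, `middle`).
#' @export
split_by_vertex <- function(records, vertex) {
  stopifnot(is.data.frame(records), "ca" %in% names(records),
            is.finite(vertex))
  if (vertex < min(records$ca) || vertex > max(records$ca))
    warning("vertex ", signif(vertex, 5),
            " lies outside the observed age range [",
            min(records$ca), ", ", max(records$ca), "]")
  records$age_band <- factor(ifelse(records$ca < vertex, "youth",
                                    "middle"),
                             levels = c("youth", "middle"))
  records
}
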