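#' Configuration for the synthetic cohort generator
#'
#' Describes a two-group (NC = normal controls, SZ = patients) cohort
#' whose regional features carry the statistical structure the
#' brain-age pipeline assumes: a set of informative features that are
#' linear (optionally quadratic) functions of each subject's
#' *effective* brain age, an additive gender confound, and a majority of
#' pure-noise features. For controls the effective brain age equals
#' chronological age (CA) exactly; for patients it deviates by a
#' quadratic brain-age-gap curve
#' \deqn{effAge - CA = a (CA - c)^2 + d}
#' with curvature `a` (years/year^2), vertex `c` (years) and offset `d`
#' (years).
#'
#' @param n_nc,n_sz Group sizes. Defaults mirror the reference study
#'   cohort (205 controls, 138 patients; see
#'   [reference_cohort_counts()]).
#' @param age_min,age_max Age range in years (uniform sampling).
#' @param n_informative_linear,n_informative_quadratic Number of
#'   features that depend linearly / quadratically on effective age.
#' @param n_noise Number of pure-noise features; `NULL` (default) fills
#'   the table up to the full three-modality layout of 1430 columns.
#' @param modalities Modality layout of the feature columns.
#' @param slope_range Magnitude range (feature-units/year) of the
#'   age slopes of informative features; signs are random.
#' @param curvature_range Magnitude range (feature-units/year^2) of the
#'   quadratic age coefficients.
#' @param noise_sd Standard deviation of the per-feature Gaussian
#'   noise. `NULL` (default) calibrates it so that the fraction of age
#'   variance recoverable from the informative features equals
#'   `target_explained_var` (see Details).
#' @param target_explained_var Explainable fraction of age variance used
#'   when `noise_sd = NULL`; default 0.85.
#' @param gender_effect_sd SD of the per-feature gender coefficients
#'   (gender coded 0/1; effect applied to informative features).
#' @param bag_coeff_a,bag_vertex_c,bag_offset_d Quadratic BAG curve of
#'   the patient group: curvature (must be >= 0), vertex age, and offset
#'   at the vertex. Defaults (0.01, 47.33, 1) place the vertex in the
#'   late forties with an elevated gap in young patients.
#' @param integer_ages Round sampled ages to whole years (default TRUE,
#'   matching integer age-band reporting).
#' @param seed Integer seed; identical config + seed gives a
#'   byte-identical table.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_nc = 205L, n_sz = 138L,
                          age_min = 20, age_max = 60,
                          n_informative_linear = 30L,
                          n_informative_quadratic = 10L,
                          n_noise = NULL,
                          modalities = c("sMRI", "fMRI", "DTI"),
                          slope_range = c(0.5, 1.5),
                          curvature_range = c(0.005, 0.02),
                          noise_sd = NULL,
                          target_explained_var = 0.85,
                          gender_effect_sd = 0.5,
                          bag_coeff_a = 0.01,
                          bag_vertex_c = 47.33,
                          bag_offset_d = 1,
                          integer_ages = TRUE,
                          seed = 1L) {
  all_names <- build_feature_names(modalities)
  if (is.null(n_noise))
    n_noise <- length(all_names) - n_informative_linear -
      n_informative_quadratic
  cfg <- list(n_nc = as.integer(n_nc), n_sz = as.integer(n_sz),
              age_min = age_min, age_max = age_max,
              n_informative_linear = as.integer(n_informative_linear),
              n_informative_quadratic = as.integer(n_informative_quadratic),
              n_noise = as.integer(n_noise),
              modalities = modalities,
              slope_range = slope_range,
              curvature_range = curvature_range,
              noise_sd = noise_sd,
              target_explained_var = target_explained_var,
              gender_effect_sd = gender_effect_sd,
              bag_coeff_a = bag_coeff_a,
              bag_vertex_c = bag_vertex_c,
              bag_offset_d = bag_offset_d,
              integer_ages = isTRUE(integer_ages),
              seed = as.integer(seed))

  nums <- c(cfg$age_min, cfg$age_max, cfg$slope_range, cfg$curvature_range,
            cfg$gender_effect_sd, cfg$bag_coeff_a, cfg$bag_vertex_c,
            cfg$bag_offset_d, cfg$target_explained_var)
  if (any(!is.finite(nums)))
    stop("cohort_config: all numeric parameters must be finite",
         call. = FALSE)
  if (!is.null(cfg$noise_sd) &&
      (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0))
    stop("cohort_config: `noise_sd` must be finite and >= 0",
         call. = FALSE)
  if (cfg$age_min >= cfg$age_max)
    stop("cohort_config: `age_min` must be < `age_max`", call. = FALSE)
  counts <- c(cfg$n_nc, cfg$n_sz, cfg$n_informative_linear,
              cfg$n_informative_quadratic, cfg$n_noise)
  if (any(is.na(counts)) || any(counts < 0L))
    stop("cohort_config: counts must be >= 0", call. = FALSE)
  if (cfg$bag_coeff_a < 0)
    stop("cohort_config: `bag_coeff_a` must be >= 0", call. = FALSE)
  if (cfg$gender_effect_sd < 0)
    stop("cohort_config: `gender_effect_sd` must be >= 0", call. = FALSE)
  n_feat <- cfg$n_informative_linear + cfg$n_informative_quadratic +
    cfg$n_noise
  if (n_feat < 1L || n_feat > length(all_names))
    stop("cohort_config: total feature count must be between 1 and ",
         length(all_names), call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# interleave canonical names round-robin across modalities so that any
# prefix of the returned order spreads over every modality present
.round_robin_names <- function(modalities) {
  nm <- build_feature_names(modalities)
  mod <- sub(":.*$", "", nm)
  pos <- stats::ave(seq_along(nm), mod, FUN = seq_along)
  nm[order(pos, match(mod, .modalities))]
}

#' Generate a synthetic NC/SZ cohort
#'
#' Draws demographics (uniform ages, Bernoulli(0.5) gender), computes
#' each subject's effective brain age (equal to CA in controls; CA plus
#' the quadratic gap curve in patients), and fills the feature columns:
#' informative features are `intercept + slope * effAge`
#' (`+ curvature * effAge^2` for the quadratic subset)
#' `+ gamma * gender + N(0, noise_sd)`; noise features are
#' `intercept + N(0, noise_sd)`. Informative features are spread
#' round-robin across the modalities so every modality subset carries
#' signal.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synth_cohort` with elements
#'   \describe{
#'     \item{table}{the feature table (validated data.frame),}
#'     \item{truth}{a `ground_truth` object recording per-subject
#'       effective ages and per-feature generating coefficients.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  n <- config$n_nc + config$n_sz
  if (n < 1L) stop("empty cohort", call. = FALSE)
  group <- c(rep("NC", config$n_nc), rep("SZ", config$n_sz))
  subject_id <- c(sprintf("NC_%04d", seq_len(config$n_nc)),
                  sprintf("SZ_%04d", seq_len(config$n_sz)))
  age <- stats::runif(n, config$age_min, config$age_max)
  if (config$integer_ages) age <- round(age)
  gender <- stats::rbinom(n, 1L, 0.5)
  education <- round(stats::runif(n, 6, 18))

  bag_true <- ifelse(group == "SZ",
                     config$bag_coeff_a * (age - config$bag_vertex_c)^2 +
                       config$bag_offset_d,
                     0)
  eff_age <- age + bag_true

  k_lin <- config$n_informative_linear
  k_quad <- config$n_informative_quadratic
  k_inf <- k_lin + k_quad
  p <- k_inf + config$n_noise

  rr <- .round_robin_names(config$modalities)[seq_len(p)]
  role <- c(rep("linear", k_lin), rep("quadratic", k_quad),
            rep("noise", config$n_noise))

  intercept <- stats::rnorm(p, 0, 5)
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  slope <- numeric(p)
  curvature <- numeric(p)
  if (k_inf > 0L)
    slope[seq_len(k_inf)] <-
      stats::runif(k_inf, config$slope_range[1], config$slope_range[2]) *
      sgn(k_inf)
  if (k_quad > 0L)
    curvature[k_lin + seq_len(k_quad)] <-
      stats::runif(k_quad, config$curvature_range[1],
                   config$curvature_range[2]) * sgn(k_quad)
  gender_coef <- numeric(p)
  if (k_inf > 0L && config$gender_effect_sd > 0)
    gender_coef[seq_len(k_inf)] <-
      stats::rnorm(k_inf, 0, config$gender_effect_sd)

  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    # calibrate so the best linear read-out of age from the informative
    # features leaves (1 - v) of the age variance unexplained:
    # sigma^2 / mean_i sum_j f_j'(age_i)^2 = (1 - v) * Var(age)
    if (k_inf == 0L) {
      noise_sd <- 1
    } else {
      deriv2 <- vapply(seq_len(k_inf), function(j) {
        (slope[j] + 2 * curvature[j] * eff_age)^2
      }, numeric(n))
      info <- mean(rowSums(deriv2))
      var_age <- (config$age_max - config$age_min)^2 / 12
      v <- config$target_explained_var
      noise_sd <- sqrt((1 - v) * var_age * info)
    }
  }

  X <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  X <- sweep(X, 2L, intercept, `+`)
  if (k_inf > 0L) {
    idx <- seq_len(k_inf)
    X[, idx] <- X[, idx] + outer(eff_age, slope[idx]) +
      outer(gender, gender_coef[idx])
    if (k_quad > 0L) {
      qi <- k_lin + seq_len(k_quad)
      X[, qi] <- X[, qi] + outer(eff_age^2, curvature[qi])
    }
  }
  colnames(X) <- rr

  canon <- build_feature_names(config$modalities)
  ord <- rr[order(match(rr, canon))]
  table <- data.frame(subject_id = subject_id, group = group, age = age,
                      gender = gender, education = education,
                      stringsAsFactors = FALSE)
  table <- cbind(table, as.data.frame(X[, ord, drop = FALSE],
                                      optional = TRUE))
  names(table) <- c("subject_id", "group", "age", "gender", "education",
                    ord)
  table <- validate_feature_table(table)

  truth <- structure(
    list(subjects = data.frame(subject_id = subject_id, group = group,
                               age = age, effective_age = eff_age,
                               bag_true = bag_true,
                               stringsAsFactors = FALSE),
         features = data.frame(feature = rr, role = role,
                               intercept = intercept, slope = slope,
                               curvature = curvature,
                               gender_coef = gender_coef,
                               stringsAsFactors = FALSE),
         noise_sd = noise_sd,
         config = unclass(config)),
    class = "ground_truth")

  structure(list(table = table, truth = truth), class = "synth_cohort")
}

#' Noise-implied brain-age error floor of a synthetic cohort
#'
#' Lower bound on the achievable out-of-sample mean absolute error of
#' any age predictor on a cohort generated by [generate_cohort()]. With
#' informative features \eqn{x_j = f_j(A) + \epsilon_j},
#' \eqn{\epsilon_j \sim N(0, \sigma^2)} independent, the best unbiased
#' estimate of age A from the features has standard deviation
#' \eqn{\sigma / \sqrt{\sum_j f_j'(A)^2}}; the implied MAE floor is
#' \eqn{\sqrt{2/\pi}} times its average over the cohort's ages.
#'
#' @param truth A `ground_truth` object.
#' @return MAE floor in years (`Inf` when no informative features).
#' @export
noise_floor_mae <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  f <- truth$features
  inf <- f$role != "noise"
  if (!any(inf)) return(Inf)
  a <- truth$subjects$effective_age
  deriv2 <- vapply(which(inf), function(j) {
    (f$slope[j] + 2 * f$curvature[j] * a)^2
  }, numeric(length(a)))
  sd_opt <- truth$noise_sd / sqrt(rowSums(deriv2))
  sqrt(2 / pi) * mean(sd_opt)
}

#' Write the generator's ground truth as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Analyzed-sample arithmetic after quality exclusions
#'
#' @param n_recruited,n_excluded Nonnegative integer counts (vectors
#'   recycle as usual).
#' @return `n_recruited - n_excluded`.
#' @export
apply_exclusions <- function(n_recruited, n_excluded) {
  if (any(n_recruited < 0) || any(n_excluded < 0) ||
      any(n_excluded > n_recruited))
    stop("exclusions must satisfy 0 <= excluded <= recruited",
         call. = FALSE)
  n_recruited - n_excluded
}

#' Reference cohort sizes mirrored by the generator defaults
#'
#' Participant flow of the clinical study cohort the default synthetic
#' cohort emulates: 154 patients and 209 controls recruited, of whom 16
#' patients and 4 controls were excluded for excessive head motion,
#' leaving 138 patients and 205 controls in the analysis.
#'
#' @return A data.frame with columns `group`, `recruited`, `excluded`,
#'   `analyzed`.
#' @export
reference_cohort_counts <- function() {
  recruited <- c(SZ = 154L, NC = 209L)
  excluded <- c(SZ = 16L, NC = 4L)
  data.frame(group = names(recruited),
             recruited = as.integer(recruited),
             excluded = as.integer(excluded),
             analyzed = apply_exclusions(recruited, excluded),
             row.names = NULL, stringsAsFactors = FALSE)
}
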