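#' Fit train-anchored z-score normalization
#'
#' Computes per-feature mean `u` and standard deviation `s` from the
#' training subjects only; [apply_zscore()] then transforms any table
#' with `Z = (x - u) / s` using these *training* statistics, never
#' recomputing them on test rows. Features whose training SD falls below
#' `eps` are flagged degenerate and either dropped (default) or passed
#' through as zero, per `degenerate`.
#'
#' @param train Training feature table.
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @param degenerate What to do with zero-variance features when
#'   applying: `"drop"` (default) or `"zero"`.
#' @param eps Degeneracy threshold on the SD.
#' @return An object of class `normalization_stats`.
#' @export
fit_zscore <- function(train, sd_type = c("sample", "population"),
                       degenerate = c("drop", "zero"), eps = 1e-12) {
  sd_type <- match.arg(sd_type)
  degenerate <- match.arg(degenerate)
  X <- .feature_matrix(train)
  if (nrow(X) < 2L)
    stop("fit_zscore needs at least 2 training subjects", call. = FALSE)
  u <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  if (sd_type == "population")
    s <- s * sqrt((nrow(X) - 1) / nrow(X))
  degen <- names(s)[s < eps]
  if (length(degen))
    message("fit_zscore: ", length(degen), " degenerate (zero-SD) ",
            "feature(s) flagged; action = ", degenerate)
  structure(list(mean = u, sd = s, degenerate = degen,
                 action = degenerate, sd_type = sd_type,
                 train_ids = as.character(train$subject_id)),
            class = "normalization_stats")
}

#' Apply train-anchored z-scoring
#'
#' @param table Feature table whose feature columns match the stats.
#' @param stats A [fit_zscore()] result.
#' @return The table with features replaced by z-scores (degenerate
#'   features dropped or zeroed per the stats' action).
#' @export
apply_zscore <- function(table, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  feats <- feature_cols(table)
  if (!setequal(feats, names(stats$mean)))
    stop("feature names do not match the normalization stats",
         call. = FALSE)
  keep <- setdiff(feats, stats$degenerate)
  X <- as.matrix(table[, keep, drop = FALSE])
  Z <- sweep(sweep(X, 2L, stats$mean[keep]), 2L, stats$sd[keep], `/`)
  out <- table
  out[keep] <- as.data.frame(Z, optional = TRUE)
  if (length(stats$degenerate)) {
    if (stats$action == "drop") {
      out <- out[, setdiff(names(out), stats$degenerate), drop = FALSE]
    } else {
      out[stats$degenerate] <- 0
    }
  }
  out
}

#' Fit the gender-confound model
#'
#' Per-feature ordinary least squares of the feature on gender (0/1)
#' over the training subjects; [apply_remove_gender()] replaces each
#' feature by its residual from this train-fitted regression, leaving
#' demographics untouched. By construction training residuals are
#' orthogonal to the gender regressor.
#'
#' @param train Training feature table; both gender levels must be
#'   present.
#' @return An object of class `confound_model` with per-feature
#'   `intercept` and `gender_coef`.
#' @export
fit_remove_gender <- function(train) {
  g <- train$gender
  if (length(unique(g)) < 2L)
    stop("fit_remove_gender: training data must contain both genders",
         call. = FALSE)
  X <- .feature_matrix(train)
  G <- cbind(1, g)
  beta <- solve(crossprod(G), crossprod(G, X))   # 2 x p
  structure(list(intercept = stats::setNames(beta[1L, ], colnames(X)),
                 gender_coef = stats::setNames(beta[2L, ], colnames(X)),
                 train_ids = as.character(train$subject_id)),
            class = "confound_model")
}

#' Remove the gender confound using a train-fitted model
#'
#' @param table Feature table.
#' @param model A [fit_remove_gender()] result.
#' @return The table with each feature replaced by its residual
#'   `x - (intercept + gender_coef * gender)`.
#' @export
apply_remove_gender <- function(table, model) {
  stopifnot(inherits(model, "confound_model"))
  feats <- feature_cols(table)
  if (!setequal(feats, names(model$intercept)))
    stop("feature names do not match the confound model", call. = FALSE)
  X <- as.matrix(table[, feats, drop = FALSE])
  fitted <- outer(rep(1, nrow(X)), model$intercept[feats]) +
    outer(table$gender, model$gender_coef[feats])
  out <- table
  out[feats] <- as.data.frame(X - fitted, optional = TRUE)
  out
}

#' Serialize a fitted component to JSON
#'
#' Writes normalization stats, confound models, fitted brain-age
#' models, bias models or trajectory fits as JSON for audit and reuse.
#'
#' @param x A fitted object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_to_json <- function(x, path) {
  jsonlite::write_json(.jsonable(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.jsonable <- function(x) {
  if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    lapply(unclass(x), .jsonable)
  } else if (is.function(x)) {
    NULL
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)   # keep names as JSON object keys
  } else {
    x
  }
}
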