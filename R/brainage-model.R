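#' Brain-age pipeline configuration
#'
#' Collects the tunable choices of the estimation pipeline. The default
#' regularization strength is a fixed LASSO penalty of 0.3 on z-scored
#' features (the gaussian coordinate-descent objective
#' `1/(2n) * RSS + lambda * ||w||_1`); `alpha_mode = "cv"` instead picks
#' the penalty by k-fold cross-validation over a log-spaced grid.
#'
#' @param alpha LASSO penalty (used when `alpha_mode = "fixed"`).
#' @param alpha_mode `"fixed"` (default) or `"cv"`.
#' @param loocv_mode Placement of feature selection relative to the
#'   leave-one-out loop: `"nested"` (default; the whole pipeline —
#'   confound fit, normalization, selection, regression — is re-fitted
#'   inside every fold, so predictions are leakage-free) or `"single"`
#'   (confound fit, normalization and selection are done once on the
#'   full training table and only the regression head is
#'   cross-validated; optimistically biased, but the single selected
#'   set matches how a single reported feature count arises).
#' @param remove_gender Residualize features on gender before
#'   normalization (default TRUE).
#' @param sd_type,degenerate Passed to [fit_zscore()].
#' @param rank_deficient `"error"` (default) or `"pseudoinverse"` for
#'   rank-deficient regression designs.
#' @param path_length Number of penalty values on the internally used
#'   decreasing path ending at `alpha`.
#' @param thresh,maxit Coordinate-descent convergence tolerance and
#'   iteration cap.
#' @param cv_nfolds Folds for `alpha_mode = "cv"`.
#' @return An object of class `bap_config`.
#' @export
bap_config <- function(alpha = 0.3,
                       alpha_mode = c("fixed", "cv"),
                       loocv_mode = c("nested", "single"),
                       remove_gender = TRUE,
                       sd_type = "sample",
                       degenerate = "drop",
                       rank_deficient = c("error", "pseudoinverse"),
                       path_length = 40L,
                       thresh = 1e-7,
                       maxit = 1e5,
                       cv_nfolds = 10L) {
  stopifnot(is.numeric(alpha), alpha > 0)
  structure(list(alpha = alpha,
                 alpha_mode = match.arg(alpha_mode),
                 loocv_mode = match.arg(loocv_mode),
                 remove_gender = isTRUE(remove_gender),
                 sd_type = sd_type,
                 degenerate = degenerate,
                 rank_deficient = match.arg(rank_deficient),
                 path_length = as.integer(path_length),
                 thresh = thresh, maxit = maxit,
                 cv_nfolds = as.integer(cv_nfolds)),
            class = "bap_config")
}

#' LASSO feature selection against age
#'
#' Fits an L1-penalized linear regression of age on the (already
#' normalized) features and returns the features with nonzero
#' coefficients. With `mode = "fixed"` the penalty is `alpha`; with
#' `mode = "cv"` it is chosen by cross-validation. A penalty at or
#' above the data's critical value selects nothing; this is reported
#' with a warning (downstream regression then reduces to the training
#' mean) rather than an error.
#'
#' @param X Numeric matrix of normalized training features (columns
#'   named).
#' @param y Numeric vector of chronological ages.
#' @param alpha Penalty (fixed mode) or ignored (cv mode).
#' @param mode `"fixed"` or `"cv"`.
#' @param config A [bap_config()] supplying solver settings.
#' @return An object of class `selection_result`: `selected` (feature
#'   names), `coefficients` (their LASSO coefficients), `lambda` (the
#'   penalty used), `mode`, `n_selected`.
#' @export
select_features <- function(X, y, alpha = 0.3,
                            mode = c("fixed", "cv"),
                            config = bap_config(alpha = alpha)) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), nrow(X) >= 2L, all(is.finite(y)),
            nrow(X) == length(y))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n

  if (mode == "cv") {
    foldid <- sample(rep_len(seq_len(config$cv_nfolds), n))
    cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, standardize = FALSE,
                               foldid = foldid, thresh = config$thresh,
                               maxit = config$maxit)
    lambda <- cvfit$lambda.min
    co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  } else {
    lambda <- alpha
    if (lambda >= lmax) {
      warning("penalty ", lambda, " is at or above the full-shrinkage ",
              "limit (", signif(lmax, 4), "); no features selected")
      co <- c(mean(y), numeric(ncol(X)))
    } else {
      path <- exp(seq(log(lmax), log(lambda),
                      length.out = config$path_length))
      fit <- glmnet::glmnet(X, y, alpha = 1, lambda = path,
                            standardize = FALSE, thresh = config$thresh,
                            maxit = config$maxit)
      co <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
    }
  }
  w <- co[-1L]
  sel <- which(w != 0)
  structure(list(selected = colnames(X)[sel],
                 coefficients = stats::setNames(w[sel],
                                                colnames(X)[sel]),
                 lambda = lambda, mode = mode,
                 n_selected = length(sel)),
            class = "selection_result")
}

# Moore-Penrose pseudoinverse via SVD (used only for the configurable
# rank-deficient fallback).
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Ordinary least-squares regression head
#'
#' Fits `y ~ X` by OLS (with intercept). With zero columns the model is
#' intercept-only and predicts `mean(y)`.
#'
#' @param X Numeric matrix of selected, normalized features.
#' @param y Response (years).
#' @param rank_deficient `"error"` (default) or `"pseudoinverse"`.
#' @return An object of class `mlr_fit`: `intercept`, named `weights`.
#' @export
fit_mlr <- function(X, y, rank_deficient = c("error", "pseudoinverse")) {
  rank_deficient <- match.arg(rank_deficient)
  stopifnot(length(y) >= 2L, all(is.finite(y)))
  if (is.null(X) || ncol(X) == 0L) {
    return(structure(list(intercept = mean(y),
                          weights = stats::setNames(numeric(0),
                                                    character(0))),
                     class = "mlr_fit"))
  }
  stopifnot(is.matrix(X), nrow(X) == length(y))
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D) || nrow(D) <= ncol(X)) {
    if (rank_deficient == "error")
      stop("rank-deficient regression design (n = ", nrow(D),
           ", p = ", ncol(X), ", rank = ", qrD$rank, ")", call. = FALSE)
    beta <- as.numeric(.pinv(D) %*% y)
  } else {
    beta <- qr.coef(qrD, y)
  }
  structure(list(intercept = unname(beta[1L]),
                 weights = stats::setNames(unname(beta[-1L]),
                                           colnames(X))),
            class = "mlr_fit")
}

#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  if (length(object$weights) == 0L)
    return(rep(object$intercept, nrow(newdata)))
  as.numeric(object$intercept +
               newdata[, names(object$weights), drop = FALSE] %*%
               object$weights)
}

# ---- internal matrix-level pipeline core --------------------------------
# Operates on raw matrices for speed; the exported fit_brainage() wraps
# these results into the component objects.

.core_fit <- function(X, y, g, config) {
  p <- ncol(X)
  gender_beta <- NULL
  if (config$remove_gender) {
    if (length(unique(g)) < 2L)
      stop("gender residualization needs both genders in training data",
           call. = FALSE)
    G <- cbind(1, g)
    gender_beta <- solve(crossprod(G), crossprod(G, X))
    X <- X - G %*% gender_beta
  }
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  if (config$sd_type == "population")
    s <- s * sqrt((nrow(X) - 1) / nrow(X))
  keep <- which(s >= 1e-12)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, s[keep],
             `/`)
  selection <- select_features(Z, y, alpha = config$alpha,
                               mode = config$alpha_mode, config = config)
  mlr <- fit_mlr(Z[, selection$selected, drop = FALSE], y,
                 rank_deficient = config$rank_deficient)
  list(gender_beta = gender_beta, mu = mu, s = s, keep = keep,
       selection = selection, mlr = mlr, y_mean = mean(y))
}

.core_transform <- function(core, X, g) {
  if (!is.null(core$gender_beta))
    X <- X - cbind(1, g) %*% core$gender_beta
  keep <- core$keep
  sweep(sweep(X[, keep, drop = FALSE], 2L, core$mu[keep]), 2L,
        core$s[keep], `/`)
}

.core_predict <- function(core, X, g) {
  Z <- .core_transform(core, X, g)
  predict(core$mlr, Z)
}

#' Fit the full brain-age model on a training table
#'
#' Runs the configured pipeline on the training table (normally all
#' normal controls): gender residualization (train-fitted), z-score
#' normalization (train-anchored), LASSO feature selection against
#' chronological age, then an OLS regression head on the selected
#' features.
#'
#' @param train Training feature table.
#' @param config A [bap_config()].
#' @return An object of class `brainage_model` holding the confound
#'   coefficients, normalization stats, selection result, regression
#'   intercept and per-feature weights (years per z-unit), and the
#'   training subject ids.
#' @export
fit_brainage <- function(train, config = bap_config()) {
  stopifnot(inherits(config, "bap_config"))
  X <- .feature_matrix(train)
  core <- .core_fit(X, train$age, train$gender, config)
  structure(list(core = core,
                 selection = core$selection,
                 intercept = core$mlr$intercept,
                 weights = core$mlr$weights,
                 feature_names = colnames(X),
                 train_ids = as.character(train$subject_id),
                 config = config),
            class = "brainage_model")
}

#' @export
print.brainage_model <- function(x, ...) {
  cat(sprintf(
    "<brainage_model> %d training subjects, %d/%d features selected (penalty %.4g)\n",
    length(x$train_ids), x$selection$n_selected,
    length(x$feature_names), x$selection$lambda))
  invisible(x)
}

#' Predict brain age for new subjects
#'
#' @param object A [fit_brainage()] model.
#' @param newdata Feature table with the same feature columns as the
#'   training table.
#' @param ... Unused.
#' @return Numeric vector of predicted brain ages (years).
#' @export
predict.brainage_model <- function(object, newdata, ...) {
  feats <- feature_cols(newdata)
  if (!setequal(feats, object$feature_names))
    stop("feature columns do not match the fitted model", call. = FALSE)
  X <- .feature_matrix(newdata)[, object$feature_names, drop = FALSE]
  .core_predict(object$core, X, newdata$gender)
}

#' Leave-one-out cross-validated brain-age prediction
#'
#' Each subject's brain age is predicted by a model trained on the
#' remaining n-1 subjects. With `loocv_mode = "nested"` (default) the
#' entire pipeline — confound fit, normalization, selection, regression
#' — is re-fitted per fold; with `"single"` those stages are fitted once
#' on all rows and only the OLS head is cross-validated (computed
#' exactly through the hat-matrix identity for leave-one-out OLS
#' residuals).
#'
#' @param table Feature table (normally the NC group), at least 3 rows.
#' @param config A [bap_config()].
#' @return A data.frame with columns `subject_id`, `group`, `age`, `ba`
#'   (out-of-fold brain age).
#' @export
loocv_predict <- function(table, config = bap_config()) {
  stopifnot(inherits(config, "bap_config"))
  n <- nrow(table)
  if (n < 3L)
    stop("LOOCV needs at least 3 subjects", call. = FALSE)
  X <- .feature_matrix(table)
  y <- table$age
  g <- table$gender
  ba <- numeric(n)

  if (config$loocv_mode == "single") {
    core <- .core_fit(X, y, g, config)
    Z <- .core_transform(core, X, g)
    k <- length(core$mlr$weights)
    if (k == 0L) {
      ba <- (sum(y) - y) / (n - 1)
    } else {
      D <- cbind(1, Z[, names(core$mlr$weights), drop = FALSE])
      f <- stats::lm.fit(D, y)
      h <- rowSums(qr.Q(f$qr)[, seq_len(f$rank), drop = FALSE]^2)
      if (any(1 - h < 1e-10))
        stop("leave-one-out ill-defined: a subject has leverage 1",
             call. = FALSE)
      ba <- y - f$residuals / (1 - h)
    }
  } else {
    for (i in seq_len(n)) {
      core <- tryCatch(
        .core_fit(X[-i, , drop = FALSE], y[-i], g[-i], config),
        error = function(e)
          stop("LOOCV fold ", i, " (subject ",
               table$subject_id[i], "): ", conditionMessage(e),
               call. = FALSE))
      ba[i] <- .core_predict(core, X[i, , drop = FALSE], g[i])
    }
  }
  data.frame(subject_id = as.character(table$subject_id),
             group = table$group, age = y, ba = ba,
             stringsAsFactors = FALSE)
}

#' Prediction accuracy metrics
#'
#' Mean absolute error, root mean squared error, Pearson correlation,
#' and coefficient of determination `R^2 = 1 - SSE/SST` with SSE taken
#' about the predictions and SST about `mean(ca)` (so badly calibrated
#' predictions can give negative values).
#'
#' @param ba Predicted brain ages (years).
#' @param ca Chronological ages (years).
#' @return An object of class `accuracy_report`: `n`, `mae`, `rmse`,
#'   `r`, `r2`.
#' @export
accuracy <- function(ba, ca) {
  stopifnot(length(ba) == length(ca), length(ca) >= 2L,
            all(is.finite(ba)), all(is.finite(ca)))
  if (stats::var(ca) == 0)
    stop("chronological age has zero variance; r and R^2 undefined",
         call. = FALSE)
  err <- ba - ca
  structure(list(n = length(ca),
                 mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 r = stats::cor(ba, ca),
                 r2 = 1 - sum(err^2) / sum((ca - mean(ca))^2)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> n = %d: r = %.3f, MAE = %.2f yr, R2 = %.3f, rMSE = %.2f yr\n",
    x$n, x$r, x$mae, x$r2, x$rmse))
  invisible(x)
}

#' Rank model weights by magnitude
#'
#' Orders the fitted regression weights by absolute value (descending),
#' preserving their signs in the output; ties are broken by canonical
#' feature order.
#'
#' @param model A [fit_brainage()] model.
#' @param k Number of top features to return; values larger than the
#'   selected-set size return all.
#' @return A data.frame with columns `feature`, `weight`.
#' @export
rank_weights <- function(model, k = 20L) {
  stopifnot(inherits(model, "brainage_model"))
  w <- model$weights
  canon <- build_feature_names()
  ord <- order(-abs(w), match(names(w), canon))
  k <- min(as.integer(k), length(w))
  idx <- ord[seq_len(max(k, 0L))]
  data.frame(feature = names(w)[idx], weight = as.numeric(w[idx]),
             row.names = NULL, stringsAsFactors = FALSE)
}
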