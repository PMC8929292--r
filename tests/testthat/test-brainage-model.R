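test_that("a penalty above the full-shrinkage limit selects nothing", {
  set.seed(1)
  X <- matrix(rnorm(200), 20)
  colnames(X) <- build_feature_names()[1:10]
  y <- rnorm(20, 40, 8)
  expect_warning(sel <- select_features(X, y, alpha = 1e6), "no features")
  expect_equal(sel$n_selected, 0L)
})

test_that("selection finds the single truly informative column", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 30), n)
  colnames(X) <- build_feature_names()[1:30]
  y <- rnorm(n, 40, 8)
  X[, 7L] <- (y - mean(y)) / sd(y)          # y is exactly column 7
  Z <- scale(X)
  # independent oracle: the column with maximal |correlation| with y
  oracle <- which.max(abs(cor(Z, y)))
  expect_equal(oracle, 7L, ignore_attr = TRUE)
  sel <- select_features(Z, y, alpha = 2)
  expect_true(colnames(X)[7L] %in% sel$selected)
  expect_lte(sel$n_selected, 3L)
})

test_that("a duplicated informative column leaves fitted predictions unchanged", {
  set.seed(3)
  n <- 60
  y <- rnorm(n, 40, 8)
  X <- cbind((y - mean(y)) / sd(y) + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 5), n))
  colnames(X) <- build_feature_names()[1:6]
  Z <- scale(X)
  Zdup <- cbind(Z, Z[, 1L, drop = FALSE])
  colnames(Zdup)[7L] <- build_feature_names()[7L]

  pred <- function(Zin) {
    sel <- select_features(Zin, y, alpha = 1)
    fit <- fit_mlr(Zin[, sel$selected, drop = FALSE], y)
    predict(fit, Zin)
  }
  expect_equal(pred(Z), pred(Zdup), tolerance = 1e-6)
})

test_that("the regression head solves exact linear systems", {
  x1 <- rnorm(20)
  X <- cbind(x1)
  colnames(X) <- "sMRI:GMV:001"
  fit <- fit_mlr(X, 2 * x1 + 5)
  expect_equal(unname(fit$weights), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 5, tolerance = 1e-10)
  expect_equal(predict(fit, X), 2 * x1 + 5, tolerance = 1e-10)
})

test_that("an empty selection yields the intercept-only (training mean) model", {
  y <- c(30, 35, 40, 45)
  fit <- fit_mlr(matrix(numeric(0), nrow = 4, ncol = 0), y)
  expect_equal(predict(fit, matrix(numeric(0), nrow = 3, ncol = 0)),
               rep(mean(y), 3))
})

test_that("rank-deficient designs error by default, pseudoinverse optional", {
  X <- cbind(rnorm(10), rnorm(10))
  X <- cbind(X, X[, 1L] + X[, 2L])
  colnames(X) <- build_feature_names()[1:3]
  y <- rnorm(10, 40)
  expect_error(fit_mlr(X, y), "rank-deficient")
  fit <- fit_mlr(X, y, rank_deficient = "pseudoinverse")
  expect_length(fit$weights, 3L)
  expect_true(all(is.finite(fit$weights)))
})

test_that("R-squared on training rows matches the brute-force formula", {
  set.seed(4)
  X <- matrix(rnorm(80), 40)
  colnames(X) <- build_feature_names()[1:2]
  y <- 40 + X[, 1L] * 3 + rnorm(40)
  fit <- fit_mlr(X, y)
  pred <- predict(fit, X)
  r2_brute <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(accuracy(pred, y)$r2, r2_brute, tolerance = 1e-12)
})

test_that("accuracy metrics match hand arithmetic and allow negative R2", {
  rep1 <- accuracy(c(30, 40), c(28, 44))
  expect_equal(rep1$mae, 3)
  expect_equal(rep1$rmse, sqrt(10))

  ca <- c(20, 30, 60)
  perfect <- accuracy(ca, ca)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r2, 1)

  rev_rep <- accuracy(rev(ca), ca)
  expect_lt(rev_rep$r2, 0)
  expect_gte(rev_rep$rmse, rev_rep$mae)

  expect_error(accuracy(c(1, 2), c(5, 5)), "zero variance")
})

test_that("LOOCV returns out-of-fold predictions at the n = 3 boundary", {
  tab <- make_table(matrix(rnorm(12), 3), age = c(25, 40, 55),
                    gender = c(0L, 1L, 0L))
  pred <- loocv_predict(tab, bap_config(remove_gender = FALSE,
                                        rank_deficient = "pseudoinverse"))
  expect_equal(nrow(pred), 3L)
  expect_true(all(is.finite(pred$ba)))
  expect_error(loocv_predict(tab[1:2, ], bap_config()), "at least 3")
})

test_that("LOOCV predictions are equivariant under row permutation", {
  cohort <- generate_cohort(small_cohort_config(seed = 12L, n_nc = 25L,
                                                n_sz = 0L))
  tab <- cohort$table
  cfg <- bap_config()
  p1 <- loocv_predict(tab, cfg)
  perm <- sample(nrow(tab))
  p2 <- loocv_predict(tab[perm, ], cfg)
  expect_equal(p2$ba[match(p1$subject_id, p2$subject_id)], p1$ba,
               tolerance = 1e-10)
})

test_that("single-selection LOOCV equals explicit refitting of the regression head", {
  cohort <- generate_cohort(small_cohort_config(seed = 13L, n_nc = 30L,
                                                n_sz = 0L))
  tab <- cohort$table
  fast <- loocv_predict(tab, bap_config(loocv_mode = "single"))

  # brute-force oracle: transform and select once, then refit OLS per fold
  model <- fit_brainage(tab, bap_config())
  z <- apply_remove_gender(tab, fit_remove_gender(tab))
  z <- apply_zscore(z, fit_zscore(z))
  sel <- model$selection$selected
  Z <- as.matrix(z[, sel, drop = FALSE])
  y <- tab$age
  slow <- vapply(seq_len(nrow(Z)), function(i) {
    fit <- fit_mlr(Z[-i, , drop = FALSE], y[-i])
    predict(fit, Z[i, , drop = FALSE])
  }, numeric(1L))
  expect_equal(fast$ba, slow, tolerance = 1e-8)
})

test_that("weight ranking is by magnitude with signs preserved", {
  cohort <- generate_cohort(small_cohort_config(seed = 14L, n_nc = 40L,
                                                n_sz = 0L))
  model <- fit_brainage(cohort$table, bap_config())
  model$weights <- setNames(c(-6.5, 3.8, 1.1),
                            c("sMRI:GMV:002", "sMRI:GMV:001",
                              "fMRI:ALFF:003"))
  top2 <- rank_weights(model, 2L)
  expect_equal(top2$feature, c("sMRI:GMV:002", "sMRI:GMV:001"))
  expect_equal(top2$weight, c(-6.5, 3.8))

  # ties break by canonical feature order
  model$weights <- setNames(c(2, -2), c("sMRI:WMV:001", "sMRI:GMV:005"))
  expect_equal(rank_weights(model, 2L)$feature,
               c("sMRI:GMV:005", "sMRI:WMV:001"))

  expect_equal(nrow(rank_weights(model, 0L)), 0L)
  expect_equal(nrow(rank_weights(model, 10L)), 2L)
})
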