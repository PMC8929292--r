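test_that("bias correction handles the exact-prediction and constant-offset cases", {
  ca <- c(20, 30, 40, 50, 60)

  ident <- fit_bias(ca, ca)
  expect_equal(ident$alpha, 0, tolerance = 1e-12)
  expect_equal(ident$beta, 0, tolerance = 1e-12)
  expect_equal(apply_bias(ca, ca, ident), ca, tolerance = 1e-12)

  shifted <- fit_bias(ca, ca + 5)
  expect_equal(shifted$alpha, 0, tolerance = 1e-12)
  expect_equal(shifted$beta, 5, tolerance = 1e-12)
  expect_equal(apply_bias(ca + 5, ca, shifted), ca, tolerance = 1e-12)
})

test_that("corrected gap averages exactly zero over the fitting cohort", {
  set.seed(21)
  for (i in 1:5) {
    ca <- runif(50, 20, 60)
    ba <- 10 + 0.7 * ca + rnorm(50, 0, 4)   # typical regression-to-mean bias
    bias <- fit_bias(ca, ba)
    corrected <- apply_bias(ba, ca, bias)
    expect_lt(abs(mean(corrected - ca)), 1e-8)
  }
})

test_that("bias correction is idempotent", {
  set.seed(22)
  ca <- runif(60, 20, 60)
  ba <- 12 + 0.65 * ca + rnorm(60, 0, 3)
  once <- apply_bias(ba, ca, fit_bias(ca, ba))
  again_model <- fit_bias(ca, once)
  expect_equal(again_model$alpha, 0, tolerance = 1e-10)
  expect_equal(again_model$beta, 0, tolerance = 1e-10)
  expect_equal(apply_bias(once, ca, again_model), once,
               tolerance = 1e-10)
})

test_that("prediction records keep BAG = correctedBA - CA exactly", {
  set.seed(23)
  ca <- runif(20, 20, 60)
  ba <- ca + rnorm(20)
  rec <- prediction_records(sprintf("S%02d", 1:20), "SZ", ca, ba,
                            bias = fit_bias(ca, ba))
  expect_identical(rec$bag, rec$ba_corrected - rec$ca)
})

test_that("a noiseless quadratic gap recovers its vertex exactly", {
  ca <- seq(20, 60, by = 0.5)
  bag <- 0.01 * (ca - 47.33)^2 + 1
  fit <- fit_trajectory(ca, bag, degree = 2L)
  expect_equal(trajectory_vertex(fit), 47.33, tolerance = 1e-8)
  expect_gt(fit$coefficients[["I(ca^2)"]], 0)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("a linear gap prefers the linear model by adjusted R-squared", {
  set.seed(24)
  ca <- runif(200, 20, 60)
  bag <- -0.15 * ca + 4 + rnorm(200, 0, 1.5)
  lin <- fit_trajectory(ca, bag, degree = 1L)
  quad <- fit_trajectory(ca, bag, degree = 2L)
  expect_gte(quad$r2, lin$r2)                 # nesting on raw R2
  cmp <- compare_trajectories(lin, quad)
  expect_equal(cmp$preferred$degree, 1L)
  expect_lt(abs(quad$coefficients[["I(ca^2)"]]), 0.01)
})

test_that("a constant gap leaves both fits flat", {
  set.seed(25)
  ca <- runif(50, 20, 60)
  bag <- rep(2, 50) + rnorm(50, 0, 0.5)
  bag <- bag - (bag - 2)                       # exactly constant
  lin <- fit_trajectory(ca, bag, degree = 1L)
  quad <- fit_trajectory(ca, bag, degree = 2L)
  expect_lte(lin$adj_r2, 0)
  expect_lte(quad$adj_r2, 0)
})

test_that("trajectory fitting validates its inputs", {
  expect_error(fit_trajectory(c(30, 30, 30, 30), rnorm(4), 2L),
               "degenerate")
  expect_error(fit_trajectory(c(30, 40, 50), rnorm(3), 2L),
               "n > degree")
  lin <- fit_trajectory(runif(10, 20, 60), rnorm(10), degree = 1L)
  expect_error(trajectory_vertex(lin), "quadratic")
})

test_that("the vertex split uses a strict less-than rule", {
  rec <- data.frame(ca = c(46, 47, 48))
  out <- split_by_vertex(rec, 47.33)
  expect_equal(as.character(out$age_band), c("youth", "youth", "middle"))

  # integer ages 20..60 against vertex 47.33: bands split at 47/48
  rec <- data.frame(ca = 20:60)
  out <- split_by_vertex(rec, 47.33)
  expect_equal(max(out$ca[out$age_band == "youth"]), 47)
  expect_equal(min(out$ca[out$age_band == "middle"]), 48)

  expect_warning(all_mid <- split_by_vertex(data.frame(ca = 30:40), 10),
                 "outside the observed age range")
  expect_true(all(all_mid$age_band == "middle"))
})

test_that("vertex recovery succeeds under realistic gap noise", {
  # one replicate of the recovery experiment (the full 50-seed version
  # is exercised in the acceptance suite)
  set.seed(26)
  ca <- round(runif(150, 20, 60))
  bag <- 0.01 * (ca - 47)^2 + 1 + rnorm(150, 0, 2)
  fit <- fit_trajectory(ca, bag, degree = 2L)
  expect_lt(abs(trajectory_vertex(fit) - 47), 5)
})
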