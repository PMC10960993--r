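test_that("NIPALS recovers noiseless single- and two-component systems", {
  # rank-1: X = c s', one latent variable suffices
  set.seed(31)
  conc <- runif(12, 10, 250)
  pure <- abs(rnorm(40))
  X <- conc %o% pure
  fit <- plsr_fit(X, matrix(conc, ncol = 1), n_lv = 1)
  expect_equal(unname(drop(predict(fit, X))), conc, tolerance = 1e-8)

  # two components with linearly independent pure spectra
  C <- cbind(runif(15, 10, 250), runif(15, 10, 250))
  S <- rbind(abs(rnorm(40)), abs(rnorm(40)))
  X2 <- C %*% S
  fit2 <- plsr_fit(X2, C, n_lv = 2)
  rmse <- sqrt(colMeans((predict(fit2, X2) - C)^2))
  expect_true(all(rmse < 1e-6))
})

test_that("full-rank PLSR equals the minimum-norm least squares oracle", {
  set.seed(32)
  for (i in 1:5) {
    n <- sample(6:10, 1); p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(n * 2), n)
    A <- min(n - 1, p)
    fit <- plsr_fit(X, Y, n_lv = A)
    oracle <- lsq_oracle(X, Y)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-6)
    expect_equal(unname(predict(fit, X)), unname(oracle$predict(X)),
                 tolerance = 1e-6)
  }
})

test_that("score vectors are mutually orthogonal after every fit", {
  set.seed(33)
  X <- matrix(rnorm(20 * 15), 20)
  Y <- matrix(rnorm(20 * 2), 20)
  fit <- plsr_fit(X, Y, n_lv = 6)
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-6)
})

test_that("prediction centering gives zero mean residual and y_mean at x_mean", {
  set.seed(34)
  X <- matrix(rnorm(18 * 12), 18)
  Y <- matrix(runif(18 * 2, 15, 240), 18)
  fit <- plsr_fit(X, Y, n_lv = 3)
  resid <- predict(fit, X) - Y
  expect_true(all(abs(colMeans(resid)) < 1e-8))
  expect_equal(unname(drop(predict(fit, matrix(fit$x_mean, 1)))),
               unname(fit$y_mean), tolerance = 1e-10)
  expect_error(predict(fit, X[, -1]), "grid mismatch")
  expect_error(plsr_fit(X, Y, n_lv = 0), "model error")
  expect_error(plsr_fit(X, Y, n_lv = 18), "model error")
})

test_that("cross-validation finds the true rank and is deterministic", {
  # noiseless two-component toy: RMSECV at 2 LVs tiny and below 1 LV
  d <- multilevel_design(2, 5, 15, 240, analyte_names = c("A", "B"))
  ds <- toy_dataset(d)
  pm <- preprocess(ds$spectra,
                   preprocess_config(excluded_regions = list()))
  cv <- plsr_cv(pm, d, lv_grid = 1:4, scheme = "loo")
  expect_lt(cv$overall[2], 1e-6)
  expect_lt(cv$overall[2], cv$overall[1])
  expect_identical(cv$selected_lv, 2L)

  # duplicate samples do not break leave-one-out
  X <- rbind(pm$matrix[1:6, ], pm$matrix[1, , drop = FALSE])
  Y <- rbind(d$concentrations[1:6, ], d$concentrations[1, , drop = FALSE])
  cv_dup <- plsr_cv(X, Y, lv_grid = 1:2, scheme = "loo")
  expect_true(all(is.finite(cv_dup$overall)))

  # k-fold with the same seed reproduces exactly
  cv1 <- plsr_cv(pm$matrix, d$concentrations, lv_grid = 1:3,
                 scheme = "kfold", seed = 5, k = 5)
  cv2 <- plsr_cv(pm$matrix, d$concentrations, lv_grid = 1:3,
                 scheme = "kfold", seed = 5, k = 5)
  expect_identical(cv1$rmsecv, cv2$rmsecv)
})

test_that("latent-variable selection rules behave on known curves", {
  fake <- structure(list(lv_grid = 1:4, overall = c(5, 3, 3, 4),
                         se_overall = rep(0.5, 4)), class = "plsr_cv")
  expect_identical(select_lv(fake, "global_min"), 2L)  # tie to fewer LVs
  mono <- structure(list(lv_grid = 1:4, overall = c(4, 3, 2, 1),
                         se_overall = rep(0, 4)), class = "plsr_cv")
  expect_identical(select_lv(mono, "global_min"), 4L)
  # one-SE steps back from the minimum to the simplest model within 1 SE
  near <- structure(list(lv_grid = 1:4, overall = c(5, 1.05, 1.06, 1),
                         se_overall = rep(0.1, 4)), class = "plsr_cv")
  expect_identical(select_lv(near, "one_se"), 2L)
})

test_that("parameter recovery holds across seeded protocol simulations", {
  # scaled-down protocol replicate count; noise averaging still applies
  errs <- sapply(1:10, function(s) {
    ds <- protocol_dataset(seed = 100 + s, replicates = 5)
    model <- seira_plsr(ds$spectra, ds$design, max_lv = 6)
    mean(abs(predict(model, ds$spectra) - ds$design$concentrations))
  })
  expect_lt(mean(errs), 0.02 * (240 - 15))
})
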