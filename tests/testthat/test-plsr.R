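# Exact rank-2 regression problem: X_i = u + f_i v + g_i w, y = f.
rank2_problem <- function(n = 24, p = 40, seed = 40) {
  set.seed(seed)
  u <- rnorm(p)
  v <- rnorm(p)
  w <- rnorm(p)
  f <- runif(n, 0, 100)
  g <- rnorm(n)
  X <- t(vapply(seq_len(n), function(i) u + f[i] * v + g[i] * w, numeric(p)))
  list(X = X, y = f)
}

test_that("one latent variable solves a rank-1 noise-free system exactly", {
  set.seed(41)
  w <- rnorm(30)
  S <- outer(rnorm(20), rnorm(30)) # rank-1 spectra matrix
  y <- as.numeric(S %*% w)
  fit <- pls_fit(S, y, 1)
  expect_lt(max(abs(pls_predict(fit, S) - y)), 1e-8 * max(abs(y)))
})

test_that("first NIPALS weight is the centered covariance direction X'y", {
  pr <- rank2_problem()
  fit <- pls_fit(pr$X, pr$y, 2)
  xc <- sweep(pr$X, 2, colMeans(pr$X))
  w1 <- as.numeric(crossprod(xc, pr$y - mean(pr$y)))
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(sum(w1 * fit$W[, 1])), 1, tolerance = 1e-10)
})

test_that("scores are orthogonal and b reproduces sequential prediction", {
  pp <- pure_processed()
  fit <- pls_fit(spec_matrix(pp), pp$soy_fraction, 4)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_true(all(abs(colSums(fit$W^2) - 1) < 1e-10))
  # sequential route: y_mean + T q
  seq_pred <- fit$y_mean + as.numeric(fit$scores %*% fit$q)
  expect_equal(pls_predict(fit, spec_matrix(pp)), seq_pred, tolerance = 1e-8)
})

test_that("full-component PLS equals OLS on the score space", {
  set.seed(42)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(10)
  fit <- pls_fit(X, y, n_lv = 6)
  ols <- stats::lm.fit(cbind(1, fit$scores), y - fit$y_mean)
  expect_equal(pls_predict(fit, X), fit$y_mean + ols$fitted.values,
    tolerance = 1e-8)
  # and equals the full OLS solution since the scores span the X space
  full <- stats::lm.fit(cbind(1, X), y)
  expect_equal(pls_predict(fit, X), unname(full$fitted.values), tolerance = 1e-6)
})

test_that("prediction is centered and consistent with the fit", {
  pr <- rank2_problem()
  fit <- pls_fit(pr$X, pr$y, 2)
  mean_row <- matrix(fit$x_mean, 1)
  expect_equal(pls_predict(fit, mean_row), fit$y_mean, tolerance = 1e-10)
  expect_lt(max(abs(pls_predict(fit, pr$X) - pr$y)), 1e-6)
  expect_error(pls_predict(fit, pr$X[, 1:5]), "variable count")
  expect_error(pls_fit(pr$X, rep(1, nrow(pr$X)), 1), "zero variance")
  expect_error(pls_fit(pr$X, pr$y, 200), "n_lv must be")
  clamped <- pls_predict(fit, pr$X - 10, clamp = TRUE)
  expect_true(all(clamped >= 0 & clamped <= 100))
})

test_that("cross-validation recovers the known latent dimension", {
  pr <- rank2_problem()
  sel <- select_n_lv(pr$X, pr$y, max_lv = 2, folds = 3, seed = 1)
  expect_equal(sel$n_lv, 2)
  expect_lte(sel$rmsecv[sel$n_lv], sel$rmsecv[1])
  sel2 <- select_n_lv(pr$X, pr$y, max_lv = 2, folds = 3, seed = 1)
  expect_identical(sel, sel2)
  # stratified folds: every fold spans the fraction levels
  y_lvl <- rep(c(10, 20, 40, 60, 80, 90), each = 6)
  fold <- soyspec:::stratified_folds(y_lvl, 3, seed = 2)
  for (fd in 1:3) expect_setequal(unique(y_lvl[fold == fd]), unique(y_lvl))
})

test_that("calibration R^2 is non-decreasing in the number of components", {
  pp <- pure_processed()
  X <- spec_matrix(pp)
  y <- pp$soy_fraction
  r2 <- vapply(1:5, function(k) {
    regression_metrics(y, pls_predict(pls_fit(X, y, k), X))$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("regression metrics match hand arithmetic", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  null_model <- regression_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(null_model$r2, 0)
  hand <- regression_metrics(c(0, 50, 100), c(10, 50, 90))
  expect_equal(hand$r2, 0.96)
  expect_equal(hand$rmse, sqrt(200 / 3))
  expect_error(regression_metrics(rep(5, 3), c(1, 2, 3)), "constant")
  expect_error(regression_metrics(1, 1), "2 samples")
})

test_that("calibrate degenerates correctly and generalizes on matched noise", {
  ds <- default_dataset(seed = 7)
  cal <- dplyr::filter(ds, split == "calibration")
  val <- dplyr::filter(ds, split == "validation")

  same <- pls_calibrate(cal, cal, seed = 3)
  expect_equal(same$r2_validation, same$r2_calibration, tolerance = 1e-12)

  rep <- pls_calibrate(cal, val, seed = 1)
  expect_lt(rep$rmsep, 3 * rep$rmsecv + 1e-9)
  expect_gte(rep$n_lv, 1)

  # report round-trips losslessly through JSON
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(glance(rep)), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$r2_calibration, rep$r2_calibration, tolerance = 1e-12)
  expect_equal(back$rmsep, rep$rmsep, tolerance = 1e-12)
  expect_identical(back$n_lv, as.integer(rep$n_lv))

  tidy_rep <- tidy(rep)
  expect_equal(nrow(tidy_rep), nrow(cal) + nrow(val))
  expect_s3_class(autoplot(rep), "ggplot")
})
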