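#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of a single response (soy mass
#' fraction, % w/w) on the preprocessed absorbance matrix. Components are
#' extracted by the NIPALS algorithm on the centered data: each weight
#' vector is the (normalized) covariance direction `X'y`, scores are
#' mutually orthogonal, and X and y are deflated between components. The
#' compact regression vector `b = W (P'W)^-1 q` reproduces the sequential
#' prediction exactly.
#'
#' @param X Numeric matrix (samples x variables) or a spectra tibble.
#' @param y Numeric response vector with nonzero variance.
#' @param n_lv Number of latent variables,
#'   `<= min(n_samples - 1, n_variables)`.
#' @return An object of class `"pls_model"`: `x_mean`, `y_mean`, `W`,
#'   `P`, `q`, `b`, `scores`, `n_lv`.
#' @export
pls_fit <- function(X, y, n_lv) {
  if (is.data.frame(X)) X <- spec_matrix(X)
  stopifnot(nrow(X) == length(y), n_lv >= 1)
  if (stats::sd(y) == 0) stop("response has zero variance")
  if (n_lv > min(nrow(X) - 1, ncol(X))) {
    stop("n_lv must be <= min(n_samples - 1, n_variables)")
  }
  nipals_pls1(X, y, n_lv, allow_partial = FALSE)
}

nipals_pls1 <- function(X, y, n_lv, allow_partial = FALSE) {
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  p <- ncol(X)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  Tm <- matrix(0, nrow(X), n_lv)
  for (k in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (allow_partial && k > 1) {
        n_lv <- k - 1
        W <- W[, seq_len(n_lv), drop = FALSE]
        P <- P[, seq_len(n_lv), drop = FALSE]
        q <- q[seq_len(n_lv)]
        Tm <- Tm[, seq_len(n_lv), drop = FALSE]
        break
      }
      stop("NIPALS failed at component ", k, ": residual X'y is null")
    }
    w <- w / nw
    t_k <- as.numeric(E %*% w)
    tt <- sum(t_k^2)
    p_k <- as.numeric(crossprod(E, t_k)) / tt
    q_k <- sum(f * t_k) / tt
    E <- E - tcrossprod(t_k, p_k)
    f <- f - q_k * t_k
    W[, k] <- w
    P[, k] <- p_k
    q[k] <- q_k
    Tm[, k] <- t_k
  }
  b <- W %*% solve(crossprod(P, W), q)
  structure(
    list(
      x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
      b = as.numeric(b), scores = Tm, n_lv = n_lv
    ),
    class = "pls_model"
  )
}

#' Predict soy fractions from a fitted PLS model
#'
#' `y_mean + (X_new - x_mean) %*% b`. Predictions are reported raw by
#' default; physical clamping to the `[0, 100]` %w/w range is available
#' but off, so calibration statistics reflect the model itself.
#'
#' @param model A `"pls_model"`.
#' @param X Numeric matrix or spectra tibble on the fitted variable grid.
#' @param clamp Clamp predictions into `[0, 100]`?
#' @return Numeric vector of predicted fractions, % w/w.
#' @export
pls_predict <- function(model, X, clamp = FALSE) {
  stopifnot(inherits(model, "pls_model"))
  if (is.data.frame(X)) X <- spec_matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("variable count (", ncol(X), ") does not match the model (",
      length(model$x_mean), ")")
  }
  pred <- model$y_mean + as.numeric(sweep(X, 2, model$x_mean) %*% model$b)
  if (clamp) pred <- pmin(pmax(pred, 0), 100)
  pred
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model:", x$n_lv, "latent variable(s),", length(x$x_mean), "variables\n")
  invisible(x)
}

#' @describeIn pls_fit Regression vector as a tibble (`term` = variable
#'   name, `estimate` = coefficient).
#' @param x A `"pls_model"`.
#' @param ... Unused.
#' @export
tidy.pls_model <- function(x, ...) {
  nm <- names(x$x_mean)
  tibble::tibble(
    term = if (is.null(nm)) paste0("x", seq_along(x$b)) else nm,
    estimate = x$b
  )
}

#' Regression metrics R-squared and RMSE
#'
#' `R^2 = 1 - SS_res / SS_tot` (not squared Pearson correlation) and
#' `RMSE = sqrt(mean((y - yhat)^2))`, in response units (% w/w).
#'
#' @param y_true Observed responses (>= 2 values, nonconstant).
#' @param y_pred Predicted responses.
#' @return One-row tibble with `r2` and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2) stop("need at least 2 samples")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y_true")
  ss_res <- sum((y_true - y_pred)^2)
  tibble::tibble(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((y_true - y_pred)^2)))
}

# Seeded fold assignment, stratified across response levels so every fold
# spans the concentration range.
stratified_folds <- function(y, folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, 0))
  fold <- integer(length(y))
  offset <- 0L
  for (lv in sort(unique(y))) {
    idx <- sample(which(y == lv))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Choose the number of latent variables by cross-validated RMSE
#'
#' Random-subset k-fold cross-validation (default 3 folds, stratified
#' across fraction levels). For each candidate LV count the RMSECV is the
#' root mean squared error over all held-out samples; the chosen count is
#' the smallest whose RMSECV is within 2% (relative) of the global
#' minimum — a parsimony rule that avoids fitting noise with extra
#' components.
#'
#' @param X Matrix or spectra tibble.
#' @param y Response vector.
#' @param max_lv Largest candidate LV count (capped by the training-fold
#'   rank).
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return List with `n_lv` (chosen) and `rmsecv` (named vector over
#'   candidates).
#' @export
select_n_lv <- function(X, y, max_lv = 10, folds = 3, seed = 1L) {
  if (is.data.frame(X)) X <- spec_matrix(X)
  stopifnot(max_lv >= 1, nrow(X) >= folds)
  fold <- stratified_folds(y, folds, seed)
  min_train <- nrow(X) - max(table(fold))
  max_lv <- min(max_lv, min_train - 1, ncol(X))
  err2 <- matrix(NA_real_, nrow(X), max_lv)
  fits <- lapply(seq_len(folds), function(fd) {
    hold <- fold == fd
    nipals_pls1(X[!hold, , drop = FALSE], y[!hold],
      n_lv = max_lv, allow_partial = TRUE
    )
  })
  # a fold may exhaust the data rank early; score only shared candidates
  max_lv <- min(max_lv, min(vapply(fits, function(f) f$n_lv, numeric(1))))
  err2 <- err2[, seq_len(max_lv), drop = FALSE]
  for (fd in seq_len(folds)) {
    hold <- fold == fd
    fit <- fits[[fd]]
    for (k in seq_len(max_lv)) {
      bk <- fit$W[, 1:k, drop = FALSE] %*%
        solve(
          crossprod(fit$P[, 1:k, drop = FALSE], fit$W[, 1:k, drop = FALSE]),
          fit$q[1:k]
        )
      pred <- fit$y_mean +
        as.numeric(sweep(X[hold, , drop = FALSE], 2, fit$x_mean) %*% bk)
      err2[hold, k] <- (y[hold] - pred)^2
    }
  }
  rmsecv <- sqrt(colMeans(err2))
  names(rmsecv) <- seq_len(max_lv)
  n_lv <- min(which(rmsecv <= 1.02 * min(rmsecv)))
  list(n_lv = n_lv, rmsecv = rmsecv)
}

#' Calibrate and validate the quantification model
#'
#' The full quantification workflow: fit the preprocessing chain on the
#' calibration set, apply the *fitted* chain to the validation set,
#' choose the LV count by stratified 3-fold RMSECV on the calibration
#' samples, refit on the full calibration set, and report the Table-style
#' calibration/validation statistics.
#'
#' @param cal,val Raw spectra tibbles with `soy_fraction` metadata.
#' @param band,steps,sg_window,sg_polyorder Passed to
#'   [preprocess_spectra()].
#' @param max_lv,folds,seed Passed to [select_n_lv()].
#' @return An object of class `"calibration_report"`: `r2_calibration`,
#'   `r2_validation`, `rmsecv`, `rmsep`, `n_lv`, `cv_seed`, plus the
#'   candidate `rmsecv_by_lv`, the fitted `model`, the fitted
#'   `preprocess` state, and `predictions` (tibble of both sets).
#' @examples
#' ds <- simulate_spectra(seed = 1)
#' rep <- pls_calibrate(
#'   dplyr::filter(ds, split == "calibration"),
#'   dplyr::filter(ds, split == "validation"),
#'   seed = 1
#' )
#' glance(rep)
#' @export
pls_calibrate <- function(cal, val, band = c(1700, 1071),
                          steps = c("sg", "msc", "snv", "minmax"),
                          sg_window = 11, sg_polyorder = 2,
                          max_lv = 10, folds = 3, seed = 1L) {
  stopifnot("soy_fraction" %in% names(cal), "soy_fraction" %in% names(val))
  cal_p <- preprocess_spectra(cal,
    band = band, steps = steps,
    sg_window = sg_window, sg_polyorder = sg_polyorder
  )
  val_p <- preprocess_spectra(val, model = preprocess_model(cal_p))
  Xc <- spec_matrix(cal_p)
  Xv <- spec_matrix(val_p)
  yc <- cal$soy_fraction
  yv <- val$soy_fraction

  sel <- select_n_lv(Xc, yc, max_lv = max_lv, folds = folds, seed = seed)
  fit <- pls_fit(Xc, yc, n_lv = sel$n_lv)
  pred_c <- pls_predict(fit, Xc)
  pred_v <- pls_predict(fit, Xv)
  mc <- regression_metrics(yc, pred_c)
  mv <- regression_metrics(yv, pred_v)

  structure(
    list(
      r2_calibration = mc$r2, r2_validation = mv$r2,
      rmsecv = unname(sel$rmsecv[sel$n_lv]), rmsep = mv$rmse,
      rmsec = mc$rmse, n_lv = sel$n_lv, cv_seed = as.integer(seed),
      rmsecv_by_lv = sel$rmsecv, model = fit,
      preprocess = preprocess_model(cal_p),
      predictions = dplyr::bind_rows(
        dplyr::mutate(spec_meta(cal), predicted = pred_c, set = "calibration"),
        dplyr::mutate(spec_meta(val), predicted = pred_v, set = "validation")
      )
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "PLS-R calibration (%d LV, cv seed %d)\n",
      "  R2 calibration  %.4f   RMSECV %.3f %%w/w\n",
      "  R2 validation   %.4f   RMSEP  %.3f %%w/w\n"
    ),
    x$n_lv, x$cv_seed, x$r2_calibration, x$rmsecv, x$r2_validation, x$rmsep
  ))
  invisible(x)
}

#' One-row summary of a calibration report
#'
#' @param x A `"calibration_report"`.
#' @param ... Unused.
#' @return Tibble with `r2_calibration`, `r2_validation`, `rmsecv`,
#'   `rmsep`, `n_lv`.
#' @export
glance.calibration_report <- function(x, ...) {
  tibble::tibble(
    r2_calibration = x$r2_calibration, r2_validation = x$r2_validation,
    rmsecv = x$rmsecv, rmsep = x$rmsep, n_lv = x$n_lv
  )
}

#' Per-sample predictions of a calibration report
#'
#' @param x A `"calibration_report"`.
#' @param ... Unused.
#' @return Tibble with metadata, `predicted` fraction and `set`.
#' @export
tidy.calibration_report <- function(x, ...) {
  x$predictions
}

#' Predicted-vs-actual plot for a calibration report
#'
#' @param object A `"calibration_report"`.
#' @param ... Unused.
#' @return A ggplot comparing predicted and true soy fractions for the
#'   calibration and validation sets.
#' @export
autoplot.calibration_report <- function(object, ...) {
  ggplot2::ggplot(
    object$predictions,
    ggplot2::aes(.data$soy_fraction, .data$predicted, colour = .data$set)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = "true soy fraction (% w/w)", y = "predicted soy fraction (% w/w)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
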