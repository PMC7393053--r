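#' Principal component analysis of a spectra set
#'
#' Mean-centered PCA via singular value decomposition (no variance
#' scaling: spectra arrive normalized from preprocessing). Loadings signs
#' are fixed so that each component's largest-magnitude loading is
#' positive, making score plots reproducible across platforms.
#'
#' @param spectra A (preprocessed) spectra tibble with >= 2 samples.
#' @param n_components Number of components to keep,
#'   `<= min(n_samples - 1, n_variables)`.
#' @return An object of class `"spectra_pca"` with elements `mean`,
#'   `loadings` (components x variables), `explained_variance_ratio`,
#'   `scores` (tibble of fit scores with metadata), `wavenumbers`.
#' @seealso [pca_transform()], [autoplot.spectra_pca()]
#' @export
pca_fit <- function(spectra, n_components = 2) {
  m <- spec_matrix(spectra)
  if (nrow(m) < 2) stop("PCA needs at least 2 samples")
  max_rank <- min(nrow(m) - 1, ncol(m))
  if (n_components > max_rank) {
    stop("n_components must be <= min(n_samples - 1, n_variables) = ", max_rank)
  }
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  sv <- svd(xc)
  # sign convention: largest |loading| of each component is positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2, flip, `*`)
  u <- sweep(sv$u, 2, flip, `*`)
  ratio <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  scores <- u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = n_components)
  colnames(scores) <- paste0("PC", k)
  structure(
    list(
      mean = mu,
      loadings = t(v[, k, drop = FALSE]),
      explained_variance_ratio = ratio[k],
      all_variance_ratio = ratio,
      n_components = n_components,
      scores = dplyr::bind_cols(spec_meta(spectra), tibble::as_tibble(scores)),
      wavenumbers = spec_wavenumbers(spectra)
    ),
    class = "spectra_pca"
  )
}

#' Project spectra onto fitted principal components
#'
#' Computes `(X - mean) %*% t(loadings)` for new spectra on the same
#' variable grid as the fit.
#'
#' @param model A `"spectra_pca"` from [pca_fit()].
#' @param spectra A spectra tibble with matching variables.
#' @return Tibble of metadata plus `PC1..PCk` score columns.
#' @export
pca_transform <- function(model, spectra) {
  stopifnot(inherits(model, "spectra_pca"))
  m <- spec_matrix(spectra)
  if (ncol(m) != length(model$mean)) {
    stop("variable count (", ncol(m), ") does not match the fitted model (",
      length(model$mean), ")")
  }
  scores <- sweep(m, 2, model$mean) %*% t(model$loadings)
  colnames(scores) <- paste0("PC", seq_len(model$n_components))
  dplyr::bind_cols(spec_meta(spectra), tibble::as_tibble(scores))
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(
    "PCA:", x$n_components, "components,",
    sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio)),
    "of total variance\n"
  )
  invisible(x)
}

#' Tidy a fitted spectra PCA
#'
#' @param x A `"spectra_pca"` object.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in the requested view.
#' @export
tidy.spectra_pca <- function(x, matrix = "scores", ...) {
  switch(matrix,
    scores = x$scores,
    loadings = {
      l <- t(x$loadings)
      tibble::tibble(
        wavenumber = rep(x$wavenumbers, ncol(l)),
        component = rep(seq_len(ncol(l)), each = nrow(l)),
        loading = as.vector(l)
      )
    },
    eigenvalues = tibble::tibble(
      component = seq_along(x$all_variance_ratio),
      variance_ratio = x$all_variance_ratio,
      cumulative = cumsum(x$all_variance_ratio)
    ),
    stop("matrix must be 'scores', 'loadings' or 'eigenvalues'")
  )
}

#' One-row summary of a fitted spectra PCA
#'
#' @param x A `"spectra_pca"` object.
#' @param ... Unused.
#' @return Tibble with `n_components`, `variance_explained` (fraction over
#'   the kept components), `n_samples`.
#' @export
glance.spectra_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    variance_explained = sum(x$explained_variance_ratio),
    n_samples = nrow(x$scores)
  )
}

#' Score plot of a fitted spectra PCA
#'
#' @param object A `"spectra_pca"` object.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 scores, colored by class label.
#' @export
autoplot.spectra_pca <- function(object, ...) {
  pct <- 100 * object$explained_variance_ratio
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$label)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pct[1]),
      y = sprintf("PC2 (%.1f%%)", pct[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
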