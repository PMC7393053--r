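#' Pearson kurtosis of a spectrum
#'
#' Fourth standardized moment `m4 / m2^2` with population moments
#' `mk = mean((x - mean(x))^k)`. This is the *non-excess* convention: a
#' normal distribution scores 3. Invariant under affine transforms of the
#' absorbance axis, so it is a pure shape feature.
#'
#' @param x Numeric vector, length >= 4 with nonzero variance.
#' @return Kurtosis (dimensionless).
#' @export
spectral_kurtosis <- function(x) {
  if (length(x) < 4) stop("kurtosis needs at least 4 points")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("kurtosis undefined for a flat spectrum")
  mean(xc^4) / m2^2
}

# Orthonormal wavelet decomposition filters. db4 taps are the standard
# 8-coefficient Daubechies values (4 vanishing moments).
wavelet_filters <- function(wavelet) {
  lo <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db4 = c(
      -0.010597401785069032, 0.0328830116668852,
      0.030841381835560764, -0.18703481171909309,
      -0.027983769416859854, 0.6308807679298589,
      0.7148465705529157, 0.2303778133088965
    ),
    stop("unknown wavelet: ", wavelet, " (supported: haar, db4)")
  )
  # quadrature mirror: hi[k] = (-1)^k * lo[L + 1 - k]
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(lo = lo, hi = hi)
}

#' One-level discrete wavelet transform
#'
#' Decomposes a signal into level-1 approximation (low-pass) and detail
#' (high-pass) coefficients by filter convolution and dyadic
#' downsampling. Boundaries use symmetric (edge-replicating) extension;
#' for the Haar wavelet on an even-length signal this reduces to plain
#' pairwise coefficients `d_i = (x[2i-1] - x[2i]) / sqrt(2)`.
#'
#' @param x Numeric vector, length >= 2.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @return List with numeric vectors `approx` and `detail`, each of
#'   length `ceiling(length(x) / 2)`.
#' @export
dwt_level1 <- function(x, wavelet = "db4") {
  if (length(x) < 2) stop("DWT needs at least 2 points")
  f <- wavelet_filters(wavelet)
  L <- length(f$lo)
  n <- length(x)
  nc <- ceiling(n / 2)
  # symmetric extension: L-2 samples on the left, enough on the right
  left <- if (L > 2) rev(x[seq_len(L - 2)]) else numeric(0)
  need_right <- 2 * (nc - 1) + L - (L - 2) - n
  right <- if (need_right > 0) rev(x)[seq_len(need_right)] else numeric(0)
  xp <- c(left, x, right)
  idx <- function(i) seq(2 * (i - 1) + 1, length.out = L)
  approx <- vapply(seq_len(nc), function(i) sum(f$lo * xp[idx(i)]), numeric(1))
  detail <- vapply(seq_len(nc), function(i) sum(f$hi * xp[idx(i)]), numeric(1))
  list(approx = approx, detail = detail)
}

#' Sum of high-frequency wavelet coefficients (SHW)
#'
#' The sum of *absolute* level-1 detail coefficients — a roughness
#' measure: smooth spectra score near 0, spectra with sharp structure or
#' residual noise score higher. Absolutely homogeneous:
#' `shw(c * x) = |c| * shw(x)`.
#'
#' @inheritParams dwt_level1
#' @return Non-negative scalar, absorbance units.
#' @export
shw <- function(x, wavelet = "db4") {
  sum(abs(dwt_level1(x, wavelet)$detail))
}

#' Extract classifier features from a spectra set
#'
#' Computes the two per-spectrum scalar features used as the neural
#' network input — kurtosis and SHW — and z-score standardizes them.
#' Standardization statistics are computed on the training rows only
#' (rows with `split == "train"`, falling back to all rows when no train
#' split is present) so that test data never leak into the scaling; the
#' statistics are attached as the `"feature_stats"` attribute for reuse.
#'
#' @param spectra A preprocessed spectra tibble.
#' @param wavelet Wavelet for the SHW feature.
#' @param standardize Apply z-score standardization?
#' @param stats Optional precomputed statistics (a `"feature_stats"`
#'   attribute from a previous call) to apply instead of fitting.
#' @return Tibble of metadata plus `kurtosis` and `shw` columns.
#' @export
featurize <- function(spectra, wavelet = "db4", standardize = TRUE,
                      stats = NULL) {
  m <- spec_matrix(spectra)
  feats <- tibble::tibble(
    kurtosis = apply(m, 1, spectral_kurtosis),
    shw = apply(m, 1, shw, wavelet = wavelet)
  )
  out <- dplyr::bind_cols(spec_meta(spectra), feats)
  if (standardize) {
    if (is.null(stats)) {
      ref <- if ("split" %in% names(out) && any(out$split == "train", na.rm = TRUE)) {
        dplyr::filter(out, .data$split == "train")
      } else {
        out
      }
      stats <- list(
        mean = c(kurtosis = mean(ref$kurtosis), shw = mean(ref$shw)),
        sd = c(kurtosis = stats::sd(ref$kurtosis), shw = stats::sd(ref$shw))
      )
      if (any(stats$sd == 0)) stop("feature has zero variance on the training rows")
    }
    out$kurtosis <- (out$kurtosis - stats$mean["kurtosis"]) / stats$sd["kurtosis"]
    out$shw <- (out$shw - stats$mean["shw"]) / stats$sd["shw"]
    attr(out, "feature_stats") <- stats
  }
  out
}
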