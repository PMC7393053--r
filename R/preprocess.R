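#' Restrict spectra to a wavenumber band
#'
#' The protein fingerprint band 1700-1071 cm^-1 carries the discriminative
#' amide I / amide II structure; all downstream analysis runs on it. The
#' interval is closed: on-grid boundary wavenumbers are retained.
#'
#' @param spectra A spectra tibble.
#' @param high,low Band limits in cm^-1, `high > low`.
#' @return The spectra tibble restricted to grid points in `[low, high]`,
#'   axis order preserved.
#' @export
select_band <- function(spectra, high = 1700, low = 1071) {
  if (high <= low) stop("`high` must exceed `low`")
  w <- spec_wavenumbers(spectra)
  keep <- w <= high & w >= low
  if (!any(keep)) stop("band [", low, ", ", high, "] contains no grid points")
  cols <- names(spectra)[is_spectral_name(names(spectra))]
  dplyr::select(
    spectra,
    dplyr::all_of(intersect(spec_meta_cols, names(spectra))),
    dplyr::all_of(cols[keep])
  )
}

#' Savitzky-Golay smoothing
#'
#' Moving-window least-squares polynomial smoother; reproduces any
#' polynomial signal of degree up to `polyorder` exactly. Edges are handled
#' by evaluating the local polynomial fit at off-center positions, so
#' output length equals input length without padding.
#'
#' @param x Numeric vector (one spectrum).
#' @param window Odd window length in points, `> polyorder`.
#' @param polyorder Polynomial degree.
#' @return Smoothed vector of the same length.
#' @export
sg_smooth <- function(x, window = 11, polyorder = 2) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  if (length(x) < window) stop("spectrum shorter than the filter window")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' Standard normal variate (SNV)
#'
#' Per-spectrum centering and scaling to unit sample standard deviation
#' (n-1 denominator); removes additive offset and multiplicative gain from
#' a single spectrum without a reference.
#'
#' @param x Numeric vector (one spectrum), length >= 2 with nonzero
#'   variance.
#' @return Transformed vector with mean 0 and sample SD 1.
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("SNV needs at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("SNV undefined for a flat spectrum")
  (x - mean(x)) / s
}

#' Min-max normalization
#'
#' Per-spectrum rescaling to `[0, 1]`.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`.
#' @export
minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("min-max undefined for a flat spectrum")
  (x - r[1]) / (r[2] - r[1])
}

# Multiplicative scatter correction of one spectrum against a reference:
# OLS fit x ~ a + b * reference, return (x - a) / b.
msc_correct <- function(x, reference) {
  stopifnot(length(x) == length(reference))
  rc <- reference - mean(reference)
  b <- sum(rc * (x - mean(x))) / sum(rc^2)
  if (!is.finite(b) || abs(b) < 1e-12) {
    stop("MSC failed: spectrum orthogonal to reference")
  }
  a <- mean(x) - b * mean(reference)
  (x - a) / b
}

#' Fit/apply the spectral preprocessing chain
#'
#' Applies band selection followed by the configured correction steps, in
#' order. The default chain is Savitzky-Golay smoothing, multiplicative
#' scatter correction (MSC), standard normal variate (SNV), then min-max
#' normalization, over the 1700-1071 cm^-1 fingerprint band.
#'
#' MSC needs a reference spectrum. When `model` is `NULL` the chain is
#' *fitted*: the reference is the mean of this set at the MSC stage, and
#' the fitted state is attached to the result as the
#' `"preprocess_model"` attribute (see [preprocess_model()]). Passing a
#' fitted model *applies* calibration-set statistics to new spectra, so
#' validation data are processed exactly as the calibration data were.
#'
#' @param spectra A spectra tibble.
#' @param band `c(high, low)` limits in cm^-1.
#' @param steps Character vector, ordered subset of
#'   `c("sg", "msc", "snv", "minmax")`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param model A fitted preprocess model to reuse, or `NULL` to fit.
#' @return The processed spectra tibble with attribute
#'   `"preprocess_model"`.
#' @examples
#' ds <- simulate_spectra(seed = 1)
#' cal <- preprocess_spectra(dplyr::filter(ds, split == "calibration"))
#' val <- preprocess_spectra(
#'   dplyr::filter(ds, split == "validation"),
#'   model = preprocess_model(cal)
#' )
#' @export
preprocess_spectra <- function(spectra, band = c(1700, 1071),
                               steps = c("sg", "msc", "snv", "minmax"),
                               sg_window = 11, sg_polyorder = 2,
                               model = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "preprocess_model"))
    band <- model$band
    steps <- model$steps
    sg_window <- model$sg_window
    sg_polyorder <- model$sg_polyorder
  }
  bad <- setdiff(steps, c("sg", "msc", "snv", "minmax"))
  if (length(bad)) stop("unknown preprocessing steps: ", paste(bad, collapse = ", "))

  out <- select_band(spectra, high = band[1], low = band[2])
  m <- spec_matrix(out)
  msc_reference <- if (is.null(model)) NULL else model$msc_reference
  if (!is.null(msc_reference) && length(msc_reference) != ncol(m)) {
    stop("fitted model reference does not match the selected band")
  }
  for (step in steps) {
    m <- switch(step,
      sg = t(apply(m, 1, sg_smooth, window = sg_window, polyorder = sg_polyorder)),
      msc = {
        if (is.null(msc_reference)) msc_reference <- colMeans(m)
        t(apply(m, 1, msc_correct, reference = msc_reference))
      },
      snv = t(apply(m, 1, snv)),
      minmax = t(apply(m, 1, minmax))
    )
  }
  out <- spec_set_matrix(out, m)
  attr(out, "preprocess_model") <- structure(
    list(
      band = band, steps = steps, sg_window = sg_window,
      sg_polyorder = sg_polyorder, msc_reference = msc_reference,
      wavenumbers = spec_wavenumbers(out)
    ),
    class = "preprocess_model"
  )
  out
}

#' Extract the fitted preprocessing model
#'
#' @param spectra Output of [preprocess_spectra()].
#' @return The `"preprocess_model"` attribute.
#' @export
preprocess_model <- function(spectra) {
  m <- attr(spectra, "preprocess_model")
  if (is.null(m)) stop("no preprocess model attached; run preprocess_spectra() first")
  m
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(
    "Preprocess model: band", x$band[1], "-", x$band[2], "cm^-1 (",
    length(x$wavenumbers), "points ), steps:", paste(x$steps, collapse = " -> "), "\n"
  )
  invisible(x)
}
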