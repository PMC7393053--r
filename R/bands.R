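#' Component band libraries
#'
#' Pure-component absorbance in the fingerprint region is modeled as a sum
#' of Gaussian (or Lorentzian) bands. The two default libraries encode the
#' qualitative contrast between the classes: both proteins share an amide I
#' band near 1637 cm^-1 (C=O stretch), beef shows a single strong amide II
#' band near 1549 cm^-1 (N-H bend / C-N stretch), while textured soy protein
#' shows a small amide II split into two sub-bands shifted above and below
#' 1549 cm^-1, giving soy a markedly higher amide-I/amide-II amplitude
#' ratio.
#'
#' @return A tibble with one row per band: `center` (cm^-1), `amplitude`
#'   (absorbance units), `fwhm` (full width at half maximum, cm^-1),
#'   `shape` (`"gaussian"` or `"lorentzian"`).
#' @examples
#' beef_bands()
#' @export
beef_bands <- function() {
  tibble::tribble(
    ~center, ~amplitude, ~fwhm, ~shape,
    1637, 1.00, 45, "gaussian", # amide I
    1549, 0.55, 40, "gaussian", # amide II, single
    1454, 0.20, 30, "gaussian", # CH2/CH3 bending
    1240, 0.15, 50, "gaussian", # amide III region
    1160, 0.12, 40, "gaussian" # C-O stretch
  )
}

#' @rdname beef_bands
#' @export
soy_bands <- function() {
  tibble::tribble(
    ~center, ~amplitude, ~fwhm, ~shape,
    1637, 1.00, 45, "gaussian", # amide I
    1576, 0.15, 30, "gaussian", # amide II sub-band, high side
    1524, 0.15, 30, "gaussian", # amide II sub-band, low side
    1400, 0.18, 35, "gaussian", # COO- symmetric stretch
    1160, 0.14, 40, "gaussian" # C-O stretch (polysaccharide)
  )
}

band_profile <- function(center, amplitude, fwhm, shape, grid) {
  d <- grid - center
  switch(shape,
    gaussian = amplitude * exp(-4 * log(2) * (d / fwhm)^2),
    lorentzian = amplitude / (1 + (2 * d / fwhm)^2),
    stop("unknown band shape: ", shape)
  )
}

#' Render a noise-free component spectrum from a band library
#'
#' Evaluates the sum of all band profiles on the grid. Deterministic; no
#' instrument effects are applied (see [apply_effects()]).
#'
#' @param bands Band tibble as returned by [beef_bands()] / [soy_bands()].
#' @param grid Wavenumber grid (decreasing numeric vector).
#' @param label Class label stored on the result (`"beef"`, `"soy"`, ...).
#' @param soy_fraction Mass fraction metadata, % w/w.
#' @return A one-row spectra tibble.
#' @export
render_component <- function(bands, grid = wavenumber_grid(),
                             label = NA_character_,
                             soy_fraction = NA_real_) {
  stopifnot(is.data.frame(bands))
  if (nrow(bands) > 0) {
    stopifnot(all(c("center", "amplitude", "fwhm", "shape") %in% names(bands)))
    if (any(bands$amplitude < 0)) stop("band amplitude must be >= 0")
    if (any(bands$fwhm <= 0)) stop("band fwhm must be > 0")
    out_of_range <- bands$center > max(grid) | bands$center < min(grid)
    if (any(out_of_range)) {
      stop(
        "band center outside grid range: ",
        paste(bands$center[out_of_range], collapse = ", "), " cm^-1"
      )
    }
  }
  a <- rep(0, length(grid))
  for (i in seq_len(nrow(bands))) {
    a <- a + band_profile(
      bands$center[i], bands$amplitude[i], bands$fwhm[i], bands$shape[i], grid
    )
  }
  as_spectra(a, grid, meta = tibble::tibble(
    sample_id = if (is.na(label)) "component" else label,
    label = label, soy_fraction = soy_fraction, split = NA_character_
  ))
}

#' Beer-Lambert mixing of two component spectra
#'
#' Absorbances of a binary mixture add linearly in the mass fractions of
#' the components: `(1 - f/100) * beef + (f/100) * soy` where `f` is the
#' soy fraction in % w/w.
#'
#' @param beef,soy One-row spectra tibbles on the same grid.
#' @param soy_fraction Soy mass fraction, % w/w in `[0, 100]`.
#' @return A one-row spectra tibble labeled `"mixture"` (or the pure class
#'   at the 0/100 endpoints) with `soy_fraction` recorded.
#' @export
mix_spectra <- function(beef, soy, soy_fraction) {
  stopifnot(soy_fraction >= 0, soy_fraction <= 100)
  wb <- spec_wavenumbers(beef)
  ws <- spec_wavenumbers(soy)
  if (length(wb) != length(ws) || any(wb != ws)) {
    stop("beef and soy spectra are on different grids")
  }
  f <- soy_fraction / 100
  a <- (1 - f) * spec_matrix(beef)[1, ] + f * spec_matrix(soy)[1, ]
  label <- if (soy_fraction == 0) "beef" else if (soy_fraction == 100) "soy" else "mixture"
  as_spectra(a, wb, meta = tibble::tibble(
    sample_id = sprintf("mix_%g", soy_fraction),
    label = label, soy_fraction = soy_fraction, split = NA_character_
  ))
}
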