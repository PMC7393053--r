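#' Instrument effects model
#'
#' Additive/multiplicative distortions emulating what an ATR-FTIR
#' measurement superimposes on the ideal component signal: a multiplicative
#' scatter gain, an additive offset, a gentle sloping baseline, and white
#' detector noise. These are exactly the artifacts the preprocessing chain
#' (MSC/SNV) is designed to remove.
#'
#' @param noise_sd SD of i.i.d. Gaussian noise per grid point, absorbance
#'   units (AU).
#' @param scatter_gain_sd SD of the per-spectrum gain around 1
#'   (dimensionless).
#' @param scatter_offset_sd SD of the per-spectrum additive offset, AU.
#' @param baseline_slope_sd SD of the baseline slope, AU per cm^-1.
#' @param rng_seed Integer seed making generation reproducible.
#' @return An object of class `"instrument_effects"`.
#' @export
instrument_effects <- function(noise_sd = 0.002, scatter_gain_sd = 0.05,
                               scatter_offset_sd = 0.01,
                               baseline_slope_sd = 1e-5, rng_seed = 1L) {
  sds <- c(noise_sd, scatter_gain_sd, scatter_offset_sd, baseline_slope_sd)
  if (any(sds < 0)) stop("effect standard deviations must be >= 0")
  structure(
    list(
      noise_sd = noise_sd, scatter_gain_sd = scatter_gain_sd,
      scatter_offset_sd = scatter_offset_sd,
      baseline_slope_sd = baseline_slope_sd, rng_seed = as.integer(rng_seed)
    ),
    class = "instrument_effects"
  )
}

# Deterministic seed derivation: keeps every derived seed a valid 32-bit
# integer while separating RNG streams across stages/draws.
derive_seed <- function(root, offset = 0) {
  as.integer((as.numeric(root) * 48271 + as.numeric(offset)) %% 2147483647)
}

#' Apply instrument effects to a spectrum
#'
#' Returns `gain * x + offset + slope * (w - mean(w)) + noise` with
#' `gain ~ N(1, scatter_gain_sd)`, `offset ~ N(0, scatter_offset_sd)`,
#' `slope ~ N(0, baseline_slope_sd)` and i.i.d. `N(0, noise_sd)` noise.
#' The draw is fully reproducible for a fixed `(rng_seed, draw_index)`
#' pair, so replicate measurements are indexed, not stateful.
#'
#' @param spectrum A one-row spectra tibble.
#' @param effects An [instrument_effects()] object.
#' @param draw_index Integer identifying the replicate draw.
#' @return The distorted spectrum as a one-row spectra tibble.
#' @export
apply_effects <- function(spectrum, effects = instrument_effects(),
                          draw_index = 1L) {
  stopifnot(inherits(effects, "instrument_effects"))
  w <- spec_wavenumbers(spectrum)
  x <- spec_matrix(spectrum)[1, ]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(effects$rng_seed, draw_index))
  gain <- stats::rnorm(1, 1, effects$scatter_gain_sd)
  offset <- stats::rnorm(1, 0, effects$scatter_offset_sd)
  slope <- stats::rnorm(1, 0, effects$baseline_slope_sd)
  noise <- stats::rnorm(length(x), 0, effects$noise_sd)
  spec_set_matrix(spectrum, rbind(gain * x + offset + slope * (w - mean(w)) + noise))
}

#' Mixture design for the calibration experiment
#'
#' The adulteration study spans soy fractions 0-100% w/w. The 0% and 100%
#' levels are the pure endpoints; the six interior levels are the mixtures,
#' prepared in 7 calibration replicates (6 x 7 = 42) and 3 independent
#' validation replicates (6 x 3 = 18).
#'
#' @param fraction_levels Soy fractions, % w/w, including the pure
#'   endpoints 0 and 100.
#' @param calib_reps Calibration replicates per interior (mixture) level.
#' @param valid_reps Validation replicates per interior level.
#' @return An object of class `"mixture_design"`.
#' @export
mixture_design <- function(fraction_levels = c(0, 10, 20, 40, 60, 80, 90, 100),
                           calib_reps = 7, valid_reps = 3) {
  if (length(fraction_levels) == 0) stop("fraction_levels must be non-empty")
  if (any(fraction_levels < 0 | fraction_levels > 100)) {
    stop("fractions must lie in [0, 100]")
  }
  structure(
    list(
      fraction_levels = sort(unique(fraction_levels)),
      calib_reps = calib_reps, valid_reps = valid_reps
    ),
    class = "mixture_design"
  )
}

#' Expand a mixture design into sample rows
#'
#' @param design A [mixture_design()].
#' @return Tibble with one row per prepared mixture: `soy_fraction`,
#'   `replicate`, `split` (`"calibration"` / `"validation"`).
#' @export
build_design <- function(design = mixture_design()) {
  stopifnot(inherits(design, "mixture_design"))
  interior <- setdiff(design$fraction_levels, c(0, 100))
  if (length(interior) == 0) stop("design has no mixture (interior) levels")
  cal <- tidyr::expand_grid(
    soy_fraction = interior, replicate = seq_len(design$calib_reps)
  )
  val <- tidyr::expand_grid(
    soy_fraction = interior, replicate = seq_len(design$valid_reps)
  )
  dplyr::bind_rows(
    dplyr::mutate(cal, split = "calibration"),
    dplyr::mutate(val, split = "validation")
  )
}

#' Generate a full synthetic dataset
#'
#' Renders the noise-free beef and soy component spectra, forms every
#' mixture row of the design by Beer-Lambert mixing, adds pure-class
#' spectra for the classification experiment (default 20 per class, split
#' 70/30 into train/test), and applies seeded instrument effects to each
#' sample independently.
#'
#' @param design A [mixture_design()].
#' @param effects An [instrument_effects()]; its `rng_seed` is overridden
#'   by `seed` when `seed` is given.
#' @param grid Wavenumber grid.
#' @param beef,soy Band libraries for the two components.
#' @param n_pure Pure-class samples per class.
#' @param pure_train_fraction Fraction of pure samples assigned to the
#'   training split.
#' @param seed Root seed for all randomness in the dataset.
#' @return A spectra tibble with mixtures (splits `calibration` /
#'   `validation`) and pure samples (splits `train` / `test`).
#' @examples
#' ds <- simulate_spectra(seed = 7)
#' dplyr::count(ds, label, split)
#' @export
simulate_spectra <- function(design = mixture_design(),
                             effects = instrument_effects(),
                             grid = wavenumber_grid(),
                             beef = beef_bands(), soy = soy_bands(),
                             n_pure = 20, pure_train_fraction = 0.7,
                             seed = NULL) {
  if (!is.null(seed)) effects$rng_seed <- as.integer(seed)
  beef_spec <- render_component(beef, grid, label = "beef", soy_fraction = 0)
  soy_spec <- render_component(soy, grid, label = "soy", soy_fraction = 100)

  rows <- build_design(design)
  n_train <- floor(n_pure * pure_train_fraction)
  pure <- dplyr::bind_rows(
    tibble::tibble(
      soy_fraction = 0, replicate = seq_len(n_pure),
      split = ifelse(seq_len(n_pure) <= n_train, "train", "test")
    ),
    tibble::tibble(
      soy_fraction = 100, replicate = seq_len(n_pure),
      split = ifelse(seq_len(n_pure) <= n_train, "train", "test")
    )
  )
  rows <- dplyr::bind_rows(rows, pure)

  specs <- purrr::map(seq_len(nrow(rows)), function(i) {
    base <- mix_spectra(beef_spec, soy_spec, rows$soy_fraction[i])
    apply_effects(base, effects, draw_index = i)
  })
  m <- do.call(rbind, purrr::map(specs, ~ spec_matrix(.x)[1, , drop = FALSE]))
  label <- dplyr::case_when(
    rows$soy_fraction == 0 ~ "beef",
    rows$soy_fraction == 100 ~ "soy",
    TRUE ~ "mixture"
  )
  meta <- tibble::tibble(
    sample_id = sprintf(
      "%s_f%03d_r%02d",
      substr(rows$split, 1, 3), round(rows$soy_fraction), rows$replicate
    ),
    label = label, soy_fraction = rows$soy_fraction, split = rows$split
  )
  as_spectra(m, grid, meta = meta)
}
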