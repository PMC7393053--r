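# Shared fixtures, generated in code and cached across test files.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Full default-design dataset at the study conditions (42 + 18 mixtures,
# 20 pure samples per class, default noise).
default_dataset <- function(seed = 7) {
  memo(paste0("ds", seed), simulate_spectra(seed = seed))
}

# Default-chain-preprocessed pure-class subset of default_dataset().
pure_processed <- function(seed = 7) {
  memo(paste0("pp", seed), {
    ds <- default_dataset(seed)
    preprocess_spectra(dplyr::filter(ds, label %in% c("beef", "soy")))
  })
}

# Small, fast dataset on a coarser grid for structural tests.
quick_dataset <- function(seed = 1, effects = instrument_effects()) {
  simulate_spectra(
    design = mixture_design(calib_reps = 3, valid_reps = 2),
    effects = effects,
    grid = wavenumber_grid(1800, 1000, 4),
    n_pure = 6, seed = seed
  )
}

zero_effects <- function() {
  instrument_effects(
    noise_sd = 0, scatter_gain_sd = 0, scatter_offset_sd = 0,
    baseline_slope_sd = 0
  )
}

# Peak amplitude of a spectrum row in a wavenumber window.
peak_in <- function(spectra, lo, hi) {
  w <- spec_wavenumbers(spectra)
  max(spec_matrix(spectra)[1, w >= lo & w <= hi])
}
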