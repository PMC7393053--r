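test_that("wavenumber grid is strictly decreasing with the documented length", {
  g <- wavenumber_grid()
  expect_length(g, 1801)
  expect_true(all(diff(g) == -2))
  expect_equal(range(g), c(400, 4000))
  expect_error(wavenumber_grid(400, 4000), "exceed")
  expect_error(wavenumber_grid(4000, 400, step = -1), "positive")
})

test_that("render_component evaluates band profiles exactly", {
  g <- wavenumber_grid(1800, 1400, 1)
  empty <- render_component(tibble::tibble(
    center = numeric(0), amplitude = numeric(0),
    fwhm = numeric(0), shape = character(0)
  ), g)
  expect_equal(unname(spec_matrix(empty)[1, ]), rep(0, length(g)))

  one <- tibble::tibble(center = 1637, amplitude = 1, fwhm = 40, shape = "gaussian")
  s <- render_component(one, g)
  a <- spec_matrix(s)[1, ]
  expect_identical(unname(a[g == 1637]), 1.0)
  # closed form exp(-4 ln2 (d/fwhm)^2): half maximum at center +/- fwhm/2
  expect_equal(unname(a[g == 1617]), 0.5)
  expect_equal(unname(a[g == 1657]), 0.5)
  expect_equal(unname(a[g == 1627]), exp(-4 * log(2) * (10 / 40)^2))

  expect_error(
    render_component(tibble::tibble(
      center = 900, amplitude = 1, fwhm = 40, shape = "gaussian"
    ), g),
    "900"
  )
})

test_that("Beer-Lambert mixing is a convex combination with correct endpoints", {
  g <- wavenumber_grid(1700, 1100, 2)
  beef <- render_component(beef_bands(), g, label = "beef", soy_fraction = 0)
  soy <- render_component(soy_bands(), g, label = "soy", soy_fraction = 100)

  expect_equal(spec_matrix(mix_spectra(beef, soy, 0))[1, ], spec_matrix(beef)[1, ])
  expect_equal(spec_matrix(mix_spectra(beef, soy, 100))[1, ], spec_matrix(soy)[1, ])

  b2 <- as_spectra(c(2, 0), c(1700, 1698))
  s2 <- as_spectra(c(0, 2), c(1700, 1698))
  expect_equal(unname(spec_matrix(mix_spectra(b2, s2, 50))[1, ]), c(1, 1))

  for (f in c(10, 33.3, 80)) {
    m <- spec_matrix(mix_spectra(beef, soy, f))[1, ]
    lo <- pmin(spec_matrix(beef)[1, ], spec_matrix(soy)[1, ])
    hi <- pmax(spec_matrix(beef)[1, ], spec_matrix(soy)[1, ])
    expect_true(all(m >= lo - 1e-12 & m <= hi + 1e-12))
  }
  expect_error(mix_spectra(beef, s2, 50), "different grids")
  expect_error(mix_spectra(beef, soy, 101), "soy_fraction")
})

test_that("instrument effects are reproducible and degenerate to identity", {
  g <- wavenumber_grid(1700, 1600, 2)
  s <- render_component(beef_bands()[1, ], g)
  expect_equal(apply_effects(s, zero_effects(), 3), s)

  fx <- instrument_effects(rng_seed = 42)
  d1 <- apply_effects(s, fx, draw_index = 5)
  d2 <- apply_effects(s, fx, draw_index = 5)
  expect_identical(spec_matrix(d1), spec_matrix(d2))
  d3 <- apply_effects(s, fx, draw_index = 6)
  expect_false(identical(spec_matrix(d1), spec_matrix(d3)))
  expect_error(instrument_effects(noise_sd = -1), ">= 0")
})

test_that("replicate noise draws match the stated distribution", {
  g <- wavenumber_grid(1700, 1692, 2)
  s <- as_spectra(rep(0.5, length(g)), g)
  fx <- instrument_effects(
    noise_sd = 0.002, scatter_gain_sd = 0, scatter_offset_sd = 0,
    baseline_slope_sd = 0, rng_seed = 11
  )
  draws <- vapply(
    seq_len(10000),
    function(i) spec_matrix(apply_effects(s, fx, i))[1, 1] - 0.5,
    numeric(1)
  )
  expect_lt(abs(stats::sd(draws) - 0.002) / 0.002, 0.05)
  expect_lt(abs(mean(draws)), 1e-4)
})

test_that("build_design reproduces the 42/18 sample bookkeeping", {
  d <- build_design()
  expect_equal(sum(d$split == "calibration"), 42)
  expect_equal(sum(d$split == "validation"), 18)
  expect_setequal(unique(d$soy_fraction), c(10, 20, 40, 60, 80, 90))

  one <- build_design(mixture_design(c(0, 50, 100), calib_reps = 1, valid_reps = 1))
  expect_equal(sum(one$split == "calibration"), 1)
  expect_error(build_design(mixture_design(c(0, 100))), "interior")
  expect_error(mixture_design(numeric(0)), "non-empty")
})

test_that("simulate_spectra produces the full dataset with correct metadata", {
  ds <- default_dataset(seed = 7)
  expect_equal(nrow(ds), 42 + 18 + 40)
  counts <- table(ds$split)
  expect_equal(
    as.integer(counts[c("calibration", "validation", "train", "test")]),
    c(42L, 18L, 28L, 12L)
  )
  expect_setequal(
    unique(ds$soy_fraction[ds$split == "calibration"]),
    c(10, 20, 40, 60, 80, 90)
  )
  expect_true(all(ds$soy_fraction[ds$label == "beef"] == 0))
  expect_true(all(ds$soy_fraction[ds$label == "soy"] == 100))
  # seeded determinism: bit-identical regeneration
  expect_identical(ds, simulate_spectra(seed = 7))
})

test_that("zero-noise replicates of one fraction are identical", {
  ds <- quick_dataset(seed = 1, effects = zero_effects())
  m <- spec_matrix(dplyr::filter(ds, soy_fraction == 40))
  expect_true(all(apply(m, 2, function(col) max(col) - min(col)) == 0))
})

test_that("soy amide-I/amide-II ratio exceeds beef's in the noise-free components", {
  g <- wavenumber_grid()
  beef <- render_component(beef_bands(), g)
  soy <- render_component(soy_bands(), g)
  ratio <- function(s) peak_in(s, 1600, 1680) / peak_in(s, 1500, 1600)
  expect_gt(ratio(soy), ratio(beef))
  # soy amide II is split around 1549: local minimum between two sub-peaks
  w <- spec_wavenumbers(soy)
  a <- spec_matrix(soy)[1, ]
  at <- function(x) a[which.min(abs(w - x))]
  expect_lt(at(1549), at(1576))
  expect_lt(at(1549), at(1524))
})
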