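test_that("band selection keeps the closed interval on the default grid", {
  ds <- as_spectra(matrix(1, 2, 1801), wavenumber_grid())
  sel <- select_band(ds, 1700, 1071)
  w <- spec_wavenumbers(sel)
  expect_length(w, 315)
  expect_equal(max(w), 1700)
  expect_equal(min(w), 1072)
  expect_true(all(diff(w) < 0))

  expect_identical(spec_matrix(select_band(ds, 4000, 400)), spec_matrix(ds))
  expect_error(select_band(ds, 500, 600), "exceed")
  expect_error(select_band(ds, 401.5, 400.5), "no grid points")
})

test_that("Savitzky-Golay reproduces polynomials and classical coefficients", {
  x <- seq_len(41)
  expect_equal(sg_smooth(rep(3, 41), 11, 2), rep(3, 41))
  quad <- 2 + 0.5 * x - 0.03 * x^2
  expect_equal(sg_smooth(quad, 11, 2), quad, tolerance = 1e-10)
  # interpolation limit: window = polyorder + 1 is the identity
  noisy <- sin(x / 3) + rep_len(c(0.2, -0.1), length(x))
  expect_equal(sg_smooth(noisy, 5, 4), noisy, tolerance = 1e-8)

  # classical 5-point quadratic kernel (-3, 12, 17, 12, -3)/35, frozen from
  # a direct least-squares fit of a quadratic to 5 equally spaced points
  set.seed(1)
  r <- rnorm(21)
  sm <- sg_smooth(r, 5, 2)
  for (i in 5:15) {
    expect_equal(
      sm[i],
      sum(c(-3, 12, 17, 12, -3) / 35 * r[(i - 2):(i + 2)]),
      tolerance = 1e-12
    )
  }
  expect_error(sg_smooth(r, 4, 2), "odd")
  expect_error(sg_smooth(r, 5, 5), "exceed")
  expect_error(sg_smooth(r[1:3], 5, 2), "shorter")
})

test_that("SNV centers and scales each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(50, sd = 3)
  out <- snv(x)
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(stats::sd(out) - 1), 1e-12)
  # affine invariance for positive gain
  expect_equal(snv(2.7 * x + 5), snv(x), tolerance = 1e-12)
  expect_error(snv(rep(1, 10)), "flat")
  expect_error(snv(3), "2 points")
})

test_that("MSC matches an independent least-squares oracle", {
  set.seed(3)
  ref <- exp(-((1:60) - 30)^2 / 200)
  expect_equal(soyspec:::msc_correct(ref, ref), ref)
  expect_equal(soyspec:::msc_correct(2 * ref + 1, ref), ref, tolerance = 1e-12)

  x <- 1.4 * ref - 0.3 + rnorm(60, sd = 0.05)
  co <- coef(lm(x ~ ref)) # normal-equations oracle
  expect_equal(soyspec:::msc_correct(x, ref), (x - co[[1]]) / co[[2]],
    tolerance = 1e-10)
  expect_error(soyspec:::msc_correct(rnorm(60), rep(1, 60)), "orthogonal")
})

test_that("min-max maps each spectrum onto [0, 1]", {
  expect_equal(minmax(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(4)
  x <- rnorm(30)
  out <- minmax(x)
  expect_identical(range(out), c(0, 1))
  expect_equal(minmax(out), out)
  expect_error(minmax(rep(2, 5)), "flat")
})

test_that("pipeline fit/apply semantics are consistent", {
  ds <- quick_dataset(seed = 5)
  fit <- preprocess_spectra(ds)
  model <- preprocess_model(fit)
  expect_s3_class(model, "preprocess_model")
  # applying the fitted model to the fitting set reproduces fit output
  reapplied <- preprocess_spectra(ds, model = model)
  expect_equal(spec_matrix(reapplied), spec_matrix(fit))

  # empty step list = band selection only
  bare <- preprocess_spectra(ds, steps = character(0))
  expect_identical(spec_matrix(bare), spec_matrix(select_band(ds)))

  # metadata and sample count survive every step
  expect_identical(spec_meta(fit), spec_meta(ds))
  expect_equal(nrow(fit), nrow(ds))

  # the alternative step order runs and yields normalized output
  alt <- preprocess_spectra(ds, steps = c("sg", "snv", "msc", "minmax"))
  expect_equal(unname(apply(spec_matrix(alt), 1, min)), rep(0, nrow(ds)))
  expect_error(preprocess_spectra(ds, steps = "emsc"), "unknown")
})

test_that("a fitted pipeline removes gain/offset scatter exactly", {
  ds <- quick_dataset(seed = 6, effects = zero_effects())
  cal <- preprocess_spectra(ds)
  model <- preprocess_model(cal)

  distorted <- as_spectra(
    1.1 * spec_matrix(ds) + 0.05, spec_wavenumbers(ds), spec_meta(ds)
  )
  out <- preprocess_spectra(distorted, model = model)
  expect_lt(max(abs(spec_matrix(out) - spec_matrix(cal))), 1e-6)

  # per-spectrum random gains/offsets are removed too
  set.seed(9)
  m <- spec_matrix(ds)
  m2 <- m * rnorm(nrow(m), 1, 0.1) + rnorm(nrow(m), 0, 0.05)
  out2 <- preprocess_spectra(
    as_spectra(m2, spec_wavenumbers(ds), spec_meta(ds)),
    model = model
  )
  expect_lt(max(abs(spec_matrix(out2) - spec_matrix(cal))), 1e-6)
})
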