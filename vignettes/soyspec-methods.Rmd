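---
title: "Methods: synthetic ATR-FTIR spectra and the soy-in-beef chemometrics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ATR-FTIR spectra and the soy-in-beef chemometrics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`soyspec` implements a complete chemometric workflow for one question:
given an ATR-FTIR absorbance spectrum of minced meat, is textured soy
protein present, and at what mass fraction? This vignette documents the
models behind each stage, the defaults and why they were chosen, and what
the synthetic data generator can and cannot tell you about real
measurements.

## The synthetic spectrum model

No public spectral library covers this exact beef/textured-soy system, so
the package ships a generator that emulates the measurement rather than a
fixed data file. It rests on three assumptions, each standard for
absorbance-mode FTIR of dried biological films:

1. **Band superposition.** A pure component's absorbance is a sum of
   Gaussian (optionally Lorentzian) bands, each with a center (cm⁻¹), an
   amplitude (AU) and a full width at half maximum (cm⁻¹). The Gaussian
   profile is `a·exp(−4 ln2 (Δ/fwhm)²)`, so the amplitude is attained
   exactly at the center and half of it at `center ± fwhm/2`.
2. **Beer–Lambert linearity.** A binary mixture at soy fraction *f* (%
   w/w) absorbs `(1 − f/100)·A_beef + (f/100)·A_soy` at every
   wavenumber. This ignores component interactions (protein–protein
   hydrogen-bonding shifts), which is the usual first-order model for
   quantitative IR calibration.
3. **Multiplicative/additive instrument effects.** Each measured spectrum
   is `gain·A + offset + slope·(ν − ν̄) + ε` with gain ~ N(1, 0.05),
   offset ~ N(0, 0.01 AU), slope ~ N(0, 10⁻⁵ AU/cm⁻¹) and white noise
   ε ~ N(0, 0.002 AU) per point. Gain and offset emulate the variable
   contact between sample and ATR crystal (the reason MSC/SNV exist);
   the noise level corresponds to a well-averaged scan (many co-added
   interferograms).

The default band libraries encode the qualitative class contrast that is
visible in real spectra of these materials: both components share the
amide I band at 1637 cm⁻¹; beef carries a single amide II band at
1549 cm⁻¹ with a little over half the amide I amplitude; textured soy
protein instead shows a *small, split* amide II (sub-bands at 1576 and
1524 cm⁻¹, amplitude 0.15 each), so its amide-I/amide-II amplitude ratio
is several times larger than beef's. The remaining bands (1454, 1400,
1240, 1160 cm⁻¹) fill in plausible fingerprint structure. The exact
amplitudes are free parameters of the emulation — there is no public
numeric reference to fit them to — and they were fixed once, from the
qualitative description above, before any downstream results were read.

The grid spans 4000–400 cm⁻¹ in 2 cm⁻¹ steps (1801 points): a 4 cm⁻¹
instrument resolution digitized at half the resolution, the common
convention. The study design mirrors a realistic wet-lab layout: six
interior mixture levels {10, 20, 40, 60, 80, 90} % w/w with 7
calibration replicates (42 samples) and 3 independent validation
replicates (18 samples), plus 20 pure spectra per class of which 70% are
tagged `train` and 30% `test`. All randomness flows from a single root
seed, split deterministically per stage and per replicate draw, so a
dataset is bit-reproducible.

**What the generator does not emulate:** wavelength-dependent ATR
penetration depth, water-vapor and CO₂ lines, detector nonlinearity,
batch-to-batch biological variation in meat composition, and any
nonlinear mixing chemistry. Passing results on synthetic data therefore
demonstrate that the *pipeline* is correct and well-conditioned at
realistic noise, not that a real instrument will reach the same figures.

## Preprocessing

Analysis is restricted to the 1700–1071 cm⁻¹ fingerprint band (closed
interval; 315 points on the default grid), where the discriminative
amide structure lives and away from the water-dominated stretch region.
The correction chain, applied per spectrum and in this order by default:

* **Savitzky–Golay smoothing** — window 11 points, polynomial order 2.
  The window (~22 cm⁻¹) is well under the narrowest band width
  (30 cm⁻¹ fwhm), so bands are preserved while point noise is attenuated.
  Edges are handled by off-center evaluation of the same local
  polynomial fit, so no padding is invented and polynomials up to the
  filter order pass through exactly.
* **MSC** — each spectrum is regressed on a reference (the mean spectrum
  of the *fitting* set) and the fitted offset and gain are removed:
  `(x − a)/b`. This inverts the instrument's affine distortion exactly.
* **SNV** — per-spectrum centering and scaling to unit sample standard
  deviation (n−1 denominator).
* **Min–max** — per-spectrum rescaling to [0, 1]. Applied per spectrum,
  not per wavenumber, consistent with its role beside MSC/SNV as a
  spectrum normalizer.

Applying both MSC and SNV is unusual (they target the same artifact);
the chain keeps both because each is individually required behaviour,
and the second application is close to idempotent. The order
SG → MSC → SNV → min–max (scatter-model removal before variance scaling)
is the default; the step list is fully configurable and the alternative
SNV-before-MSC order is exercised in the tests.

The chain has *fit/apply* semantics: `preprocess_spectra()` without a
model fits (and records) the MSC reference; passing the fitted model
applies calibration statistics unchanged to validation data. For
noise-free spectra the fitted chain is invariant (≤ 10⁻⁶) under
gain/offset distortion of the raw input — the property the chain exists
to provide.

## PCA

Mean-centered PCA via SVD, no variance scaling (the spectra arrive
normalized). Loading signs are fixed so each component's
largest-magnitude element is positive, making score plots reproducible
across BLAS implementations. Explained-variance ratios are singular
values squared over their total for the centered matrix.

## Features: kurtosis and SHW

Two scalar shape features summarize each preprocessed spectrum for the
classifier:

* **Kurtosis** — Pearson (non-excess) `m₄/m₂²` with population moments;
  a normal-shaped intensity distribution scores 3. The convention is
  stated explicitly because the excess form (normal = 0) is equally
  common. Kurtosis is affine-invariant, so it reads pure band shape.
* **SHW** — the sum of *absolute* level-1 discrete wavelet transform
  detail coefficients (default wavelet `db4`; `haar` is supported and
  used for hand-verifiable tests). A signed sum was rejected: details of
  a smooth signal nearly cancel, so a signed sum is ≈ 0 regardless of
  class and carries no information. Boundaries use symmetric extension;
  for Haar on even length the transform reduces to pairwise differences
  `(x₂ᵢ₋₁ − x₂ᵢ)/√2`.

On the default generator, kurtosis separates the two classes by a very
wide margin (tens of pooled standard deviations — beef's single strong
amide II changes the intensity distribution shape markedly), while SHW
at level 1 is dominated by residual post-smoothing noise and contributes
little separation on its own. Both are kept: the feature pair is the
designed classifier interface, the separation happens to be carried by
one of them at these noise settings. Features are z-score standardized
using training-row statistics only, which backpropagation needs for
stable step sizes.

## Classification: four-layer MLP

The classifier is a feed-forward multilayer perceptron with exactly four
layers — input (2 features), two hidden layers, one sigmoid output — and
is trained by full-batch gradient descent (plain backpropagation) on
squared error with targets beef = 0 / soy = 1. Defaults: hidden sizes
8 and 4, learning rate 0.1, 2000 epochs, Glorot-uniform initialization
from a seed. These are deliberately the smallest stable settings that
separate the default classes; there is no momentum, adaptive optimizer
or early stopping, keeping the training dynamics auditable (the gradient
is verified against central finite differences in the tests).

Performance is estimated by **random-subset cross-validation**: 10
stratified splits holding out `floor(n_class · 0.3)` samples per class,
a freshly initialized network per split, derived seeds throughout.
Reported metrics are accuracy and **MAPE on class codes** beef = 1 /
soy = 2 — the codes are shifted off zero so the relative error in MAPE
is defined; under hardened (0.5-threshold) predictions MAPE = 0 is
exactly equivalent to 100% accuracy. An optional majority-vote ensemble
of independently seeded networks is available (`ensemble` argument,
default 1) for the "modular" combination idea; at default settings a
single network already saturates the task.

## Quantification: NIPALS PLS1

The soy fraction is regressed on the preprocessed calibration spectra by
PLS1, computed with the NIPALS recursion on centered data: weight
`w ∝ Eᵀf`, score `t = Ew`, loadings `p = Eᵀt/tᵀt`, `q = fᵀt/tᵀt`,
deflation of both blocks per component. Scores of distinct components
are orthogonal (checked to 10⁻⁸), and the compact regression vector
`b = W(PᵀW)⁻¹q` reproduces sequential prediction. Predictions are
reported raw (no clamping to [0, 100]) so calibration statistics
describe the model; a `clamp` flag exists for production use.

The number of latent variables is chosen by **stratified 3-fold
cross-validated RMSE** over candidates 1–10: folds are stratified across
fraction levels so every fold spans the concentration range, and the
chosen count is the *smallest* whose RMSECV is within 2% (relative) of
the minimum — a parsimony rule, since past the true factor dimension
extra components fit noise. If a training fold exhausts the data rank
early, candidates are truncated to what every fold supports. Reported
figures follow the standard calibration-transfer discipline: the
preprocessing model and the PLS model are fitted on calibration data
only and applied unchanged to the validation set; R² is defined as
`1 − SS_res/SS_tot` (not squared Pearson correlation), RMSECV/RMSEP in
% w/w. The pure endpoints (0 and 100%) are excluded from the default
calibration set — the 42-sample design is the six interior mixture
levels — but `run_end_to_end()` can append the pure training spectra via
the `include_pure` config switch.

## Numerical choices and degenerate inputs

* SNV, min–max and kurtosis reject flat (zero-variance) spectra with an
  error rather than returning NaN.
* MSC rejects spectra orthogonal to the reference (|slope| < 10⁻¹²).
* NIPALS stops with the offending component named if the residual
  covariance collapses; LV selection tolerates early rank exhaustion.
* The MLP raises an error on non-finite loss (divergence) instead of
  returning garbage weights.
* Stratified CV splitting redraws with a derived seed (and a message) if
  a split ever misses a class; with the default class sizes this cannot
  trigger.
* All derived seeds stay below 2³¹ and every stochastic routine restores
  the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the full default design:
1801-point grid, 315-point fingerprint band, 60 mixture + 40 pure
spectra, 10 CV subsets × 2000 training epochs, and a 20-replicate
bias study for the PLS calibration. The complete suite runs in a few
minutes on one core; structural tests use a coarser 201-point grid with
reduced replication to keep iteration fast.

## Known limitations

* The band libraries are plausibility-calibrated, not fitted to
  measured spectra; absolute amplitudes and widths should not be
  interpreted quantitatively.
* Results on synthetic data bound the pipeline's correctness, not a real
  instrument's performance; expect real RMSEP to be worse than the
  synthetic figure because biological replicate variation is not
  modeled.
* Level-1 SHW is noise-sensitive by construction; at substantially
  higher noise levels than the default, classification would lean
  entirely on kurtosis.
* PLS1 only (single response); no interval variable selection or outlier
  diagnostics (leverage, Q residuals).
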