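Package: soyspec
Title: ATR-FTIR Chemometrics for Detecting Textured Soy Protein in Beef
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native chemometrics pipeline for identifying and
    quantifying textured soy protein adulteration of beef meat from ATR-FTIR
    absorbance spectra. Provides a seeded synthetic-spectrum generator built
    on Gaussian/Lorentzian band models with Beer-Lambert mixing and
    instrument scatter effects; a fit/apply preprocessing chain
    (Savitzky-Golay smoothing, multiplicative scatter correction, standard
    normal variate, min-max normalization) over the fingerprint band
    1700-1071 cm-1; mean-centered PCA for class visualization; per-spectrum
    kurtosis and level-1 wavelet roughness (SHW) features; a four-layer
    back-propagation multilayer perceptron classifier with random-subset
    cross-validation; and NIPALS PLS1 regression with 3-fold RMSECV latent
    variable selection for mass-fraction calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
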