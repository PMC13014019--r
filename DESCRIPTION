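Package: nirsicpp
Title: Simulation, Preprocessing and Classification of Prefrontal fNIRS
    for Precocious-Puberty Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for block-design prefrontal
    functional near-infrared spectroscopy (fNIRS) studies of idiopathic
    central precocious puberty (ICPP). Simulates dual-wavelength raw
    intensity cohorts with hemodynamic-response-convolved task activity and
    physiological noise; screens channel quality by coefficient of
    variation; converts intensities to oxy-, deoxy- and total-hemoglobin
    concentration changes via the modified Beer-Lambert law; removes drift,
    physiological oscillations and motion artifacts (polynomial detrending,
    zero-phase Butterworth low-pass, temporal derivative distribution
    repair); maps task activation with a canonical-HRF general linear model
    and FDR-controlled channel-wise t tests; extracts five feature families
    (negative-correlation channel-pair statistics, per-channel principal
    components, their combination, empirical-mode-decomposition components,
    and GLM activation amplitudes); trains and evaluates five classical
    classifier families with grid-search cross-validation; and augments
    training sets with a conditional denoising diffusion probabilistic
    model over hemoglobin trial segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    signal,
    e1071,
    MASS,
    rpart,
    randomForest,
    class,
    car,
    jsonlite,
    yaml,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
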