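Package: soarflight
Title: Soaring-Flight Classification and Sea-Crossing Weather Analysis for
    Raptor Biologging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-frequency GPS, accelerometer and
    magnetometer bursts from soaring raptors crossing open water. Classifies
    flight behaviour (flapping, gliding, thermal soaring) from sensor
    signatures, recognises soaring-pattern geometry (spiral, staircase,
    s-shape) from turn diameters, annotates tracks with gridded weather to
    derive wind support, side wind and the surface-air temperature difference
    used as a thermal-uplift proxy, detects sea crossings and builds
    resting-versus-departure decision tables, and fits binomial mixed models
    with all-subsets model averaging, variance-partition R-squared and k-fold
    predictive accuracy. A synthetic-trajectory generator with known ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    lme4,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
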