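Package: divekin
Title: Kinematic Dive Features and Environmental Models for Biologging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for interpreting the diving behaviour of air-breathing
    marine "surfacers" (sea turtles, sea snakes, cetaceans) from multi-sensor
    biologging records. Raw tri-axial acceleration, magnetometer and depth
    channels are condensed into 1 Hz kinematic series (zero-offset corrected
    depth, dynamic body acceleration, tag-corrected pitch, tilt-compensated
    heading), dives are detected and split into descent, bottom and ascent
    phases, and sixteen per-dive variables are assembled into a feature
    matrix. Unsupervised cluster scans, correlation-matrix principal
    component analysis with bootstrap loading stability, and additive mixed
    models with cyclic diel smooths, tidal covariates, per-animal random
    intercepts and AR(1) residual whitening link the resulting dive features
    to season, time of day and tide. A multi-sensor deployment simulator
    with planted ground truth makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
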