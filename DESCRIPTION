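Package: mirtraj
Title: Directional Statistics for MicroRNA Expression Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Asks whether a time course of microRNA expression moves in a
    well-defined direction. Expression series are floored, filtered by mean
    intensity, log-ratio normalized against a naive reference sample and
    projected by principal component analysis; per-time-point displacement
    directions are then summarized on the unit sphere by the smallest
    enclosing spherical cap and the spherical standard deviation, and
    Monte-Carlo random-walk null models assign P-values to trajectory
    directionality, to the discrimination between treatment groups, and to
    the proximity of responses across mouse strains. Includes a "digital
    knockout" operation for assessing miR subsets and a synthetic-data
    generator that emulates the design of an ischemia reperfusion injury
    microarray time-course study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
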