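Package: flockreml
Title: Pedigree-Based Variance Components for Methane and Maternal Sheep Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedigree-based quantitative-genetic analysis of
    repeated records on sheep: reading and validating pedigrees, building the
    numerator relationship matrix and its sparse inverse, deriving respiration
    chamber methane traits (g/day, yield per kg dry matter intake, molar
    fraction of total gas) and maternal ewe traits with the associated
    record-level filters, assembling design structures for the repeatability
    animal model, estimating variance components by average-information REML
    (univariate and bivariate), and simulating multi-flock sire-family data
    with known parameters for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
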