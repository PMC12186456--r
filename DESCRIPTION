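Package: grazefit
Title: Numerical and Functional Response Analysis for Protist Grazing
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing numerical-response
    (NR) and functional-response (FR) bottle experiments with phagotrophic
    aquatic protists. Converts cell volumes to carbon biomass, derives
    per-well growth, grazing, ingestion and clearance rates from count data
    against predator-free controls, fits threshold numerical-response and
    generalized Holling disk (type I/II/III) functional-response models by
    nonlinear least squares with small-sample AICc model selection,
    discriminates FR types from the proportion of prey ingested, checks gross
    growth efficiency for consistency, plans geometric dilution series, and
    simulates whole experiments with realistic pipetting and subsample
    counting noise for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
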