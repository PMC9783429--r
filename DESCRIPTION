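Package: sadapt
Title: Sympatric-Allopatric Tests for Local Adaptation and Adaptive Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies local adaptation (genetic effects) and
    adaptive phenotypic plasticity (plastic effects) from reciprocal
    common-environment trait data using the dual-generation
    sympatric-allopatric (SA) contrast. Fits sequential ANOVA models with
    sum-to-zero contrasts and residualized SA covariates, reports F tests
    for the genetic and plastic SA terms against the relevant interaction
    remainder mean squares, the phi fractions of interaction variance
    explained, residualized genetic/plastic effect means, weighted
    correlations with Fisher-z confidence intervals, and a simulation
    engine for false-positive-rate and power studies under Normal,
    Poisson, and Binomial response models.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
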