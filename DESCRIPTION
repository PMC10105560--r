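Package: kinabund
Title: Kin-Based Abundance Estimation for Harvested Mammal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based annual-cycle pedigree simulation for terrestrial
    game species with overlapping generations (red deer and wild boar presets),
    together with four census-size estimators that operate on
    genetically-identified parent-offspring pairs: a naive close-kin
    mark-recapture (CKMR) Lincoln-Petersen estimator of adult abundance, a
    per-sex genetic capture-mark-recapture (g-CMR) estimator of total
    abundance, a method-of-moments estimator of breeding-female abundance from
    mother-daughter pairs, and the Creel-Rosenblatt pedigree estimator (CRE) of
    adult abundance. An evaluation harness runs replicated simulation x
    resampling experiments over fecundity and sampling-intensity grids and
    summarises relative bias and coefficient of variation of each estimator.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
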