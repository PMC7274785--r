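Package: mousecal
Title: Multi-Site Mouse Indirect Calorimetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mouse indirect calorimetry cohorts
    collected across multiple institutional sites. Computes energy
    expenditure and derived metrics from gas exchange (Weir and Lusk
    formulas, respiratory exchange ratio, energy intake and balance),
    partitions recordings into acclimation and post-acclimation
    photoperiods, screens datasets for documented multi-site anomalies
    (inverse mass effects, constant food intake, mismatched energy
    formulas, short runs, transient outliers), fits per-site wild-type
    reference regressions with body composition, temperature and
    activity covariates, decomposes explained variance by LMG relative
    importance, attributes residual variance to institutional site, and
    scores knockout strains and interventions as residuals from the
    wild-type model in units of the wild-type residual standard
    deviation. Includes a seeded synthetic-cohort generator emulating
    the statistical structure of large phenotyping consortium datasets
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
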