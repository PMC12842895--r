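Package: phenorate
Title: Rates, Neutral Null Models and Variability Comparisons for
    Phenotypic Evolution in Fossil Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evolutionary quantitative genetics tools for continuous-trait
    time series such as hominin endocranial volume: per-generation rates of
    evolution in haldanes and on the mean-standardized (natural-log) scale,
    log-rate/log-interval regression to classify directional change, random
    walk and stasis, neutral null models for phenotypic divergence (constant
    -heritability drift and mutation-drift equilibrium) with z-scores and
    tail probabilities, selection-gradient estimation from observed rates via
    the mean-standardized Lande equation, and coefficient-of-variation
    inference (small-sample correction, pooled within-sex CV, bootstrap and
    asymptotic confidence intervals for CV differences, comparative
    percentile placement). Includes seeded generators for synthetic trait
    lineages and comparative CV tables so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
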