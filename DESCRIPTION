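Package: marshequiv
Title: Functional Equivalence Scoring for Constructed Living Shorelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-metric functional-equivalence analysis for paired
    comparisons of constructed living shorelines and natural fringing
    marshes. Provides replicate-level study simulation, per-metric site
    summaries (soil-core depth weighting, quadrat densities, nekton
    aggregates, taxonomic distinctness, camera and visual-survey effort
    adjustment), paired Z-scores standardized by local or regional pooled
    standard deviations, net equivalence scores, a Bayesian logarithmic
    age model with leave-one-out cross-validation (PSIS-LOO) model
    comparison and posterior predictive checks, and point-transect
    distance sampling with half-normal and hazard-rate detection
    functions, AIC selection and effective detection radius estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
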