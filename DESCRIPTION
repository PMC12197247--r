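Package: dvtmatch
Title: Multi-Method Propensity Matching and Ensemble-Weighted
    Counterfactual Effects for Anticoagulation Therapy Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing combined anticoagulation plus
    venoprotective therapy (CAV) against standard anticoagulation (SAT) in
    deep vein thrombosis cohorts. Implements four propensity-score
    matching algorithms (nearest-neighbour with caliper, Mahalanobis
    distance, exact-constrained optimal assignment, and genetic search
    over covariate weights), a five-dimension ensemble-weighting scheme
    for combining matched datasets, T-learner counterfactual estimation of
    individual and average treatment effects with a double-residual
    cross-check, Rosenbaum-bounds sensitivity analysis, thresholded
    correlation network construction, and a seeded synthetic-cohort
    generator with known injected effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
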