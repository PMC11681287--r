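Package: emsdemand
Title: Small-Area Ambulance and Emergency-Department Demand Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates annual hospital emergency-department (ED) visits and
    ambulance needs per neighborhood in a large city when no aggregated
    emergency-medical-services data exist. Builds day and night populations
    from a neighborhood registry and municipal commuter inflows, estimates
    period probabilities and per-capita ED visit rates from survey and
    hospital-sample data, computes per-area ambulance-use rates by naive,
    population-weighted naive, and Monte Carlo (parametric binomial
    bootstrap) estimators with confidence intervals and a one-sample t-test
    comparison, and combines the parameters into scenario tables of annual
    ambulance and emergency-care demand. Includes a synthetic-data generator
    so the full pipeline is testable without access to the original survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
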