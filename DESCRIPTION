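Package: mspop
Title: Multi-State Population Projection of Chronic Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the burden of chronic disease in an ageing
    population with a discrete-time multi-state cohort-component model.
    Interval-censored biennial panel observations of health states (healthy,
    one chronic condition, multimorbidity, dead) are annualised by pseudo-data
    expansion, one-year age-sex-race-specific transition probabilities are
    estimated by multinomial logistic regression with cluster-bootstrap
    uncertainty, and the estimated rates drive a population projection with
    births, life-table deaths below age 50, and a calibrated constant net
    migration rate. Includes a synthetic panel and demographics generator
    with known ground-truth dynamics, a microsimulation oracle for validating
    the expected-value engine, and reporting helpers that aggregate
    trajectories into age-band burden tables with ensemble intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
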