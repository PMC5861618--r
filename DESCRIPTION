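Package: nutriopt
Title: Allocative Efficiency Analysis for Childhood Stunting Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-timestep compartmental model of childhood stunting and
    under-5 mortality, stratified by age band, height-for-age category and
    breastfeeding practice, linked to logistic cost-coverage functions for six
    nutrition interventions and an adaptive stochastic descent budget
    optimizer. Supports calibration to observed mortality and stunting,
    projection of baseline and counterfactual coverage scenarios,
    single-region and multi-region (geospatial) optimization of a fixed
    annual nutrition budget against objectives such as maximizing the number
    of children reaching age five alive and not stunted, budget-outcome
    curves, and a YAML databook format with synthetic Bangladesh-like
    fixtures for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
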