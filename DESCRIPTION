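Package: segeostat
Title: Geostatistical Modelling and Mapping of Plasma Selenium Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based geostatistical analysis of plasma selenium
    concentrations from nationally structured micronutrient surveys.
    Simulates nested survey designs (individuals within households within
    georeferenced clusters) with spatially correlated cluster effects and
    lognormal outcomes; fits the nested spatial linear mixed model with a
    Matern correlation function by residual maximum likelihood, with the
    smoothness parameter chosen by profile likelihood; computes ordinary
    kriging prediction distributions of individual-level log concentration
    on a grid; maps probabilities of falling below selenoprotein activity
    thresholds on a calibrated verbal scale; validates fitted models by
    leave-one-out cross-validation with standardized squared prediction
    error diagnostics; and produces stratified prevalence and summary
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
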