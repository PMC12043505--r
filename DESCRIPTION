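Package: baychron
Title: Bayesian Radiocarbon Calibration, Phase Models and Age-Depth Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian chronometric modelling for archaeological and
    palaeoenvironmental radiocarbon dates. Calibrates single determinations
    against terrestrial or marine calibration curves, fits multi-phase
    depositional models with 'sigma' or 'uniform' boundaries and a general
    outlier model by Metropolis-within-Gibbs sampling, estimates local marine
    reservoir offsets (Delta-R) from stratigraphically paired charcoal and
    shell dates, and fits a non-monotonic Bayesian age-depth regression with
    full posterior imputation at undated depths. Includes seeded simulators
    for calibration curves, phased occupation sites, paired reservoir data
    sets and disturbed sediment cores, so that every estimator can be
    exercised against data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
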