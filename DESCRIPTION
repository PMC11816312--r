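Package: bufferguts
Title: Buffer-Compartment GUTS Survival Models for Event-Based Terrestrial Exposure
Version: 0.1.0
Authors@R:
    person("bufferguts", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Toxicokinetic-toxicodynamic (TKTD) survival modelling for
    above-ground terrestrial invertebrates such as honeybees. Implements the
    reduced General Unified Threshold models of Survival (GUTS-RED) with
    stochastic-death (SD) and individual-tolerance (IT) death mechanisms, and
    a buffer-compartment variant (BufferGUTS) in which an exoskeleton/gut
    buffer is filled instantly by event-based exposure and drains with
    first-order kinetics into scaled damage. Provides event-based exposure
    discretization, toxic-unit normalization via log-logistic dose-response
    fits, Bayesian calibration of survival count data with an adaptive
    Metropolis sampler, posterior-predictive checks and the EFSA model
    performance metrics (PPC, NRMSE, SPPE), a synthetic survival-data
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
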