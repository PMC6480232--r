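Package: plumekrig
Title: Inverse Emission Estimation and Residual Kriging for Low-Cost PM2.5 Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Turns period-averaged PM2.5 measurements from a sparse network of
    low-cost sensors into (a) inferred emission rates for prescribed source
    regions and (b) finely resolved concentration maps. Steady-state Gaussian
    plume kernels (finite line sources at arbitrary wind angle, area sources by
    wind-perpendicular line decomposition) are run with unit emissions and
    period-averaged into a receptor-by-category transfer matrix; category
    emission rates are estimated by non-negative least squares with residual
    bootstrap confidence intervals; model-observation residuals are interpolated
    by simple kriging and added back to the modeled mean field ("residual
    kriging") to map concentrations on a regular grid. Includes a synthetic
    valley scenario generator, model-evaluation metrics (factor-of-two fraction,
    geometric standard deviation of the observed/modeled ratio, r-squared) and
    leave-one-out cross-validation of the mapping methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
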