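Package: mitowave
Title: Modelling and Analysis of Mitotic Waves in Sensory Organ Progenitor Rows
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies and models the centrifugal wave of mitoses observed in
    rows of Drosophila sensory organ progenitors (SOPs). Provides a
    contact-inhibition ("contagion") ordinary-differential-equation model of
    division timing along a cell row with threshold-triggered division events,
    a descriptive wave-metrics pipeline (first-divider identification, signed
    metric ranks, rank-time regression, wave rate as the mean absolute inverse
    slope), least-squares estimation of the model's degradation and inhibition
    parameters from observed rank-time curves, and a synthetic notum generator
    with genotype presets for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
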