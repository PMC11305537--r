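Package: itspower
Title: Power, Bias and Precision of Interrupted Time Series Designs via Monte Carlo Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the performance of interrupted time series
    (ITS) designs estimated by segmented regression when the number of
    measurement occasions is small. Generates synthetic longitudinal
    test-score panels under several intervention shapes (step change, slope
    change, both, or two step changes plus a slope change), fits a catalogue
    of ordinary-least-squares segmented-regression model variants including
    deliberately underfit and overfit specifications, and summarises
    empirical power, absolute bias and precision of the intervention
    coefficients over replicated simulation cells. Includes scenario-grid
    construction, heatmap-ready aggregation and minimum-requirement
    (sample size by time points) power frontiers.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
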