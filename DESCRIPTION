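Package: fluctscale
Title: Taylor's Law Scaling of Forest Disturbance Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Taylor's-law (fluctuation scaling) relationships
    between the temporal mean and variance of annual forest disturbance
    rates across spatial grains, disturbance agents and biomes. Provides
    log-log ordinary least squares fits of the mean-variance power law with
    permutation null tests, comparison against expectations under
    independent sampling from skewed distributions (log-normal moment
    calibration, the skewness/CV analytical solution, bootstrap envelopes),
    and forecasts of exceedance probabilities and return periods of extreme
    disturbance pulses under rising mean rates. Includes a synthetic
    cell-year disturbance generator with an optional self-limiting
    (fuel/host depletion) feedback, grid aggregation utilities, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
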