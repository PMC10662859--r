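Package: crosslag
Title: Distributed Lag Non-Linear Models for Daily Counts and Weather Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Exposure-lag-response analysis of daily disease counts against
    meteorological time series. Builds cross-basis design matrices that
    combine a spline basis over exposure intensity with a spline basis over
    lag, fits overdispersed (quasi-Poisson) log-linear regressions with
    seasonal-trend splines and day-of-week adjustment, and turns the fits
    into lag-specific and lag-cumulative relative-risk curves centered at
    the fitted minimum-risk exposure. Includes a calibrated synthetic-data
    generator with a configurable true exposure-lag-response surface so the
    whole workflow can be exercised and validated without restricted
    hospital admission data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    splines,
    stats,
    utils,
    tibble,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    dplyr,
    readr
Config/testthat/edition: 3
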