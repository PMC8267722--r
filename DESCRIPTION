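Package: extremeair
Title: Extreme-Value Modeling of Unhealthy Air Pollution Events
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extreme-value analysis of air pollution index (API)
    series. Computes Malaysian sub-API indices from pollutant concentrations
    and classifies air-quality status; selects extreme observations by annual
    block maxima (BM), peaks-over-threshold (POT), or a mixed POT-BM scheme in
    which runs of threshold exceedances are declustered with a minimum
    separation (default 240 hours) and the per-cluster maximum is retained;
    fits generalized extreme-value (GEV) and generalized Pareto (GPD) models by
    L-moments or maximum likelihood with standard errors; and computes return
    levels with delta-method confidence intervals, mean-residual-life curves,
    autocorrelation and probability-plot diagnostics. Includes a seeded
    generator of synthetic hourly API-like series with clustered exceedance
    episodes for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
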