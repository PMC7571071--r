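Package: stemfill
Title: Bidirectional Recurrent Gap Filling for Stem-Moisture Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fills long contiguous gaps in uniformly sampled plant
    stem-moisture (and similar diurnal sensor) time series by recursive
    windowed one-step forecasting with long short-term memory (LSTM) and
    simple recurrent networks, trained forward from the pre-gap segment and
    backward from the time-reversed post-gap segment, and fused by equal,
    decreasing or segmented per-index weights.  Includes a covariate-driven
    multivariate variant that maps micro-environment channels (air humidity,
    photosynthetically active radiation, soil temperature) to stem moisture
    so that fill length is not limited by error accumulation, classical
    baselines (cubic spline, shape-preserving Hermite interpolation, ARMA
    and ARIMA forecasts), analytic layer parameter accounting for the
    recurrent architectures, an error-evaluation suite (maximum, minimum,
    MAE, MAPE, RMSE and thresholded error-distribution proportions), and a
    seeded synthetic generator of diurnal stem-moisture series with
    correlated environmental covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
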