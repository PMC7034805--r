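Package: distlag
Title: Distributed Lag Models and ARDL Bounds Cointegration Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits finite, polynomial (Almon), Koyck (instrumental-variables) and
    autoregressive distributed lag (ARDL) regression models for multivariate
    time series, with per-series lag removal, recursive multi-step forecasting
    with Monte Carlo prediction intervals, and a battery of absolute and
    relative forecast-accuracy measures (MASE, GMRAE, MBRAE and UMBRAE among
    them). Implements the ARDL bounds cointegration test of Pesaran, Shin and
    Smith (2001) <doi:10.1002/jae.616>: conditional error-correction model
    construction for the five deterministic-term cases, embedded asymptotic
    critical-value bounds, derived error-correction models with long-run
    coefficients, residual diagnostics and recursive-residual stability charts
    (CUSUM, CUSUM of squares, MOSUM), together with an exhaustive and a fast
    two-stage grid search for the lag orders of the test. Also provides a
    Monte Carlo rolling-correlation test of signal significance against
    correlated white noise, seedable synthetic data generators for every model
    family, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
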