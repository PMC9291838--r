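Package: rainpickup
Title: Counterfactual Precipitation from Column-Water-Vapor Pickup Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how removing a tracked moisture source (such as
    tree transpiration from the Amazon basin) from the atmosphere changes
    precipitation, using the empirical nonlinear "pickup" relation between
    hourly precipitation and column water vapor. Builds binned conditional
    quartile curves of precipitation versus column water vapor, scales
    observed precipitation by quantile ratios evaluated at counterfactual
    water-vapor levels, and provides an alternative Monte Carlo resampling
    estimator that preserves the conditional precipitation distribution.
    Includes a synthetic generator of gridded hourly climate series with a
    threshold pickup law, seasonal AR(1) column water vapor, and monthly
    transpired-fraction fields, plus aggregation, wet-day event statistics,
    seasonal and spatial diagnostics, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    lubridate,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
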