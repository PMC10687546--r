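Package: qwanat
Title: Quantitative Wood Anatomy Chronologies, Climate Response and
    Drought Legacy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Turns tracheid-level wood anatomical measurements into
    earlywood/latewood trait chronologies and intra-annual sector
    profiles, and relates them to monthly climate and drought.  Implements
    Mork's-index earlywood/latewood classification, hydraulically
    weighted mean conduit diameter, cell wall thickness and anatomical
    density trait formulas, cubic smoothing-spline detrending with a 50%
    frequency-response cutoff, autoregressive prewhitening and biweight
    robust mean chronologies, bootstrapped monthly climate-growth
    correlations, the Standardized Precipitation Evapotranspiration Index
    (SPEI) with log-logistic standardization and drought-year calendars,
    min-max normalized intra-annual profiles with loess smoothing,
    Kolmogorov-Smirnov phase contrasts, and Gini inequality with
    percentile and BCa bootstrap confidence intervals.  A synthetic-data
    generator with planted drought years and admixture-dependent drought
    effects makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    magrittr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
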