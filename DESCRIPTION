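Package: fireElev
Title: Elevational Distribution of Forest Fires and Climate Velocity of
    Vapor Pressure Deficit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify upslope shifts in forest fire activity in
    mountainous ecoregions. Computes the Bayes-normalized elevational
    distribution of burned forest from gridded burn masks, forest cover and
    a digital elevation model, and derives the Z90 statistic (90th
    percentile of the normalized annual burn elevation) and BA90 (annual
    burned area above the 90th percentile of forest elevation). Provides
    weighted quantile-regression trend estimation with year-block bootstrap
    confidence intervals, Mann-Kendall trend tests with the Hamed-Rao
    autocorrelation correction, epoch and tercile composites with
    two-sample distribution tests, warm-season vapor pressure deficit (VPD)
    aggregation and its elevational climate velocity, regression-based
    attribution of fire-elevation change to VPD trends, hypsometric
    estimates of newly fire-exposed forest area, and a seeded synthetic
    landscape/climate/fire generator with a closed-form oracle for
    validating the estimators by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
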