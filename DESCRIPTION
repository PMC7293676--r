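Package: lagcast
Title: Lagged Air-Pollution Exposure Panels, Spatial Autocorrelation and
    Combination Forecasting for Areal Health Outcomes
Version: 0.1.0
Authors@R:
    person("lagcast", "maintainers", email = "lagcast@example.org",
           role = c("aut", "cre"))
Description: Tools for county-level environmental epidemiology panels that
    link current and lagged fine particulate matter (PM2.5) exposure, at the
    local and surrounding-region scale, to areal health outcome rates such as
    lung-cancer mortality and morbidity per 100,000.  Provides a synthetic
    registry-panel generator (lattice geography, Gaussian-random-field
    exposure surfaces with AR(1) persistence, an unbalanced registry entry
    schedule), grid-to-area exposure aggregation with WHO guideline
    classification, queen-contiguity and inverse-distance spatial weights,
    Global Moran's I with normality, randomization and permutation inference,
    an 18-predictor distributed-lag design with pooled Pearson correlations,
    five forecasting models written from scratch (ridge regression, partial
    least squares, CART-style regression trees, model trees with linear
    leaves, and an inverse coefficient-of-variation combination), a repeated
    random-split evaluation protocol reporting MSE, MAE, MAPE and the Theil
    inequality coefficient with its bias/variance/covariance decomposition,
    and ordinary Kriging of forecast surfaces from a fitted variogram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
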