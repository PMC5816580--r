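Package: mativ
Title: Linking Catchment Land Use to Estuarine Benthic Vegetation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical tools linking catchment land-use intensity to the
    balance of macroalgae and seagrass in small estuaries. Implements
    collinearity screening of candidate predictors, Bayesian stochastic-search
    variable selection (spike-and-slab Gibbs sampling with posterior odds
    ratios), exact hierarchical partitioning of regression goodness-of-fit,
    and a Bayesian piecewise change-point regression of the
    macroalgae-to-total-vegetation (MA:TV) ratio on percent catchment
    fertilization, with Gelman-Rubin convergence diagnostics. Also provides
    coverage-weighted habitat-area summaries, the MA:TV statistic itself,
    quartile summaries of catchment nutrient-export rates, and a seeded
    synthetic-data generator emulating an estuary survey for testing the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
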