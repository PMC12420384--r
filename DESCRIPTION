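Package: msomscale
Title: Cross-Scale Biodiversity Loss from Multi-Species Occupancy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how biodiversity loss from land-use change
    scales from local to regional extents. Provides a synthetic-avifauna
    generator (landscapes, species ranges and traits, clustered point-count
    designs, detection histories), biogeographic covariates and clipping rules,
    a biogeographically constrained multi-species occupancy model with
    imperfect detection (MAP and MCMC fitting, posterior occupancy prediction
    under hypothetical forest and pasture scenarios), species-sensitivity and
    thresholded species-pool metrics with region-pooling scaling curves,
    hexagon-grid multiplicative beta-diversity regressions of excess regional
    loss, and generalized dissimilarity models with monotone I-splines,
    barrier covariates and Bayesian-bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
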