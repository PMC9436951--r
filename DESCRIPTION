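Package: alphagrain
Title: Multi-Grain Mapping of Vascular Plant Alpha Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for modelling and mapping local (alpha) species
    richness of vascular plants at multiple spatial grains from
    heterogeneous vegetation-plot surveys. Implements plot screening and
    formation classification, stratified geographical resampling with
    simulated survey incompleteness, principal-component predictor
    assembly, boosted regression tree ensembles with
    regression-of-observed-on-estimated (ROE) bias correction, gridded
    multi-grain prediction with hotspot, uncertainty, scaling-anomaly and
    ignorance layers, and spatially blocked cross-validation with
    variogram-based block sizing. A synthetic-world generator produces
    plot surveys with a known power-law species-area relationship over
    spatially autocorrelated environmental fields, so every stage of the
    pipeline can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    minpack.lm,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
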