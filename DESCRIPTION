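Package: invstack
Title: Stacked Ensemble Species Distribution Models for Mapping Plant
    Invasion Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for stacked ensemble species distribution
    modelling of naturalized alien plants: occurrence filtering (spatial
    deduplication, environmental-space thinning, minimum-record rule),
    pseudo-absence sampling outside a surface range envelope with
    target-group effort weighting, four-algorithm model fitting with
    spatial block cross-validation and the continuous Boyce index,
    Boyce-weighted ensembling and Boyce-maximization binarization,
    richness stacking with hotspot, turnover and coefficient-of-variation
    analytics, Whittaker biome assignment with richness-weighted kernel
    density centroids, and a synthetic virtual-species world generator
    whose known niches make truth-recovery benchmarks possible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    mgcv,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
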