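Package: hyperice
Title: UAV Hyperspectral Phenotyping Pipeline for Rice Yield Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying rice breeding lines into yield classes from
    UAV-borne hyperspectral imagery. Implements reflectance calibration against
    white/dark reference frames, spectral angle mapper (SAM) soil-background
    removal, edge-trimmed plot region-of-interest selection with non-repetitive
    pixel sampling, correlation-driven aggregation of 176 narrow bands into 22
    channels, a 41-entry vegetation-index registry, a replicate-count lodging
    index, and the intraline (leave-one-replicate-out) and interline
    (leave-one-line-per-class-out) evaluation designs with grid-searched
    gradient-boosted trees and classical baselines. A synthetic field-scene
    generator with a known sensor model provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    e1071,
    randomForest,
    rpart,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
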