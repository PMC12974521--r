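Package: wiringPI
Title: Wiring Positional Information from Connectomes and Spatial Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts paired spatial gradients of wiring positional information
    (linear combinations of regional gene expression) that best explain a binary
    directed region-to-region connectome, using canonical correlation analysis on
    paired source/target expression vectors, in the spirit of Sperry's
    chemoaffinity theory. Provides connectome reconstruction from the gradients
    with ROC/AUC evaluation against a physical-distance baseline, gene screening
    by cosine similarity with spatially-constrained surrogate null distributions,
    Moran's I and variogram spatial statistics, four connectome null models
    (global, within-block local, distance-constrained, degree-constrained), an
    expression-randomization control, and a synthetic chemoaffinity data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
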