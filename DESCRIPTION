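Package: pseudocascade
Title: Gene Expression Cascades Along Pseudotime
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Visualizes and compares multi-gene expression cascades along a
    pseudotime ordering of single cells. For each gene a cubic regression
    spline is fit to expression against pseudotime and tested for temporal
    variation by a likelihood-ratio test; Benjamini-Hochberg-retained genes
    are scaled, their zero-crossing switch points detected, and genes are
    classified into temporal patterns (increasing, decreasing, up-down,
    down-up) and ordered into a cascade by pattern complexity and first
    switch point. Supports multi-sample consistency analysis with
    switch-point confidence intervals, per-pattern and sliding-window
    (temporal) gene-set over-representation analysis, cascade heatmaps with
    marker highlighting, and a seeded synthetic-data generator with planted
    temporal patterns for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
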