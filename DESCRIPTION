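Package: adaphaar
Title: Adaptive Haar-Like Distances for Interpretable Microbiome Metric
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Phylogenetic beta-diversity metric learning for compositional
    microbiome data. Projects samples onto the Haar-like wavelet basis of a
    reference phylogeny, learns a sparse non-negative weighting of internal
    tree nodes that reproduces the affinity structure of a trained random
    forest via non-negative matching pursuit on a PCoA-extracted Gram
    target, and uses the learned metric for interpretable low-dimensional
    embedding and surrogate nearest-neighbour prediction. Includes the
    fixed Haar-like and DPCoA distances, random-forest affinity and kernel
    estimates, PERMANOVA pseudo-F, distance correlation, the corrected
    resampled t-test, and a synthetic planted-clade data generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    ranger,
    stats,
    utils
Suggests:
    biomformat,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
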