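Package: scnvbm
Title: Seed-Based Structural Covariance Network Analysis for
    Voxel-Based Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and group comparison of seed-based structural
    covariance networks (SCNs) from spatially normalized, modulated
    gray-matter density images. Provides sphere region-of-interest
    extraction at MNI coordinates, mass-univariate voxel-wise regression
    with T contrasts, Benjamini-Hochberg false-discovery-rate control
    with cluster-extent thresholding, genotype-by-seed slope-interaction
    mapping, Hardy-Weinberg and demographic scalar statistics,
    region-to-behavior Pearson correlation tables, and a synthetic-cohort
    generator that plants known covariance structure so that every stage
    of the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
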