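Package: episubtype
Title: Cross-Cohort DNA-Methylation Subtyping and Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery and cross-cohort replication of disease subtypes from
    brain DNA-methylation profiles, with downstream molecular
    characterization. Per-cohort dual-algorithm consensus clustering
    (Ward.D2 hierarchical and k-means arbitrated by normalized mutual
    information), sparse PLS-DA latent-space projection with convex-hull
    replication tests, median-profile correlation matching, subtype
    epigenome-wide association with surrogate variables and empirical-null
    (bacon-style) correction, inverse-variance meta-analysis,
    conditional-MLE odds-ratio overlap and cell-type CpG-panel enrichment,
    approximate-Bayes-factor colocalization, bulk and pseudobulk
    transcriptomic signatures with a cross-cohort consistency filter, and a
    co-methylation module eigenprobe platform-preservation check. A
    multi-cohort synthetic-data generator with known ground truth makes
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    mixOmics,
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
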