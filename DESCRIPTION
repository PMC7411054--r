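Package: phenoprofiler
Title: Phenomic Profiling of High-Content Compound Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for image-based phenomic
    profiling of multi-plate, multi-batch, multi-concentration compound
    screens: well-level aggregation of per-cell features, z-score
    normalization against DMSO vehicle controls, minimum-redundancy
    maximum-relevance (mRMR) selection of an "imaging signature" with a
    replicate-discrimination AUC stopping rule, two-criterion phenotypic
    active calling against empirical control nulls, and per
    mechanism-of-action (MoA) nearest-reference AUC-ROC scoring with
    permutation significance and Benjamini-Hochberg FDR control. Includes
    a synthetic screen generator with known ground truth, auxiliary
    expression and core-fitness calling rules, and design-of-experiment
    analyses over concentration and fluorescence-channel subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    mclust,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
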