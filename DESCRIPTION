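Package: rishSelect
Title: Marker Discovery for Tumor-Adjacent Normal Tissue from Semi-Quantitative
    RISH Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers markers that distinguish normal tissue adjacent to
    cancer (NTAC) from normal tissue adjacent to benign tumors (NTAB) from
    semi-quantitative RNA in situ hybridization (RISH) scores on tissue
    microarrays. Implements composite 0-6 scoring of cores (positive-cell
    ratio category plus staining-density category), per-gene Wilcoxon
    rank-sum testing with midranks, tie-corrected variance and exact
    enumeration for small samples, four filter ranking criteria (pooled t,
    symmetric Kullback-Leibler divergence, Bhattacharyya distance, rank-sum
    |z|), and filter-ranked incremental gene-subset selection scored by
    repeated stratified 10-fold cross-validated AUC of a linear support
    vector machine. A calibrated synthetic-cohort simulator generates
    ordinal score matrices with a prescribed per-gene class separability
    (analytic AUC) for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Classification, FeatureExtraction, GeneExpression, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
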