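Package: jgrnmf
Title: Joint Graph-Regularized Non-Negative Matrix Factorization for
    Spatial Domain Identification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies spatial domains in spatial transcriptomics data by
    factorizing a preprocessed gene-expression matrix under two graph-Laplacian
    regularizers: an adaptive gene-expression neighbor graph whose per-spot
    neighborhood size is chosen by a closed-form constrained optimization, and
    a mutual k-nearest-neighbor graph built from spot coordinates. The
    low-dimensional spot embedding is clustered with K-means into tissue
    domains. Includes 10x Visium and CSV readers, the preprocessing pipeline
    (gene filtering, per-spot normalization, highly variable gene selection,
    per-gene max scaling), clustering agreement metrics (ARI, NMI, purity), a
    Wilcoxon rank-sum marker-gene screen, and a synthetic spatial dataset
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
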