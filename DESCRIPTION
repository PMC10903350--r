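Package: scmoa
Title: Cell Subtype Classification from Single-Cell Multi-Omics with
    Omics-Level Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised cell subtype classification from single-cell
    multi-omics data (gene expression, DNA methylation, chromatin
    accessibility). Each omics layer is anchored to genes (library-size
    normalised log expression, promoter CpG-cluster mean methylation,
    gene-body accessibility sums), restricted to genes shared across all
    layers, and min-max aligned. A per-omics self-attention network embeds
    each feature, scores its importance, pools features into one context
    vector per omics, and classifies cells through a fully connected softmax
    head trained with cross-entropy. Attention scores double as
    marker-candidate rankings validated by one-way ANOVA. Includes stratified
    cross-validation with multiclass metrics (accuracy, weighted F1,
    Matthews correlation, one-vs-rest AUC), omics-combination and
    no-attention ablations, and a synthetic multi-omics generator with
    planted subtype markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
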