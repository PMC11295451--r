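Package: scMarkerEval
Title: Stability and Specificity Evaluation of Cell-Type Marker Genes in
    Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how stable and specific candidate cell-type
    marker genes are across multiple single-cell RNA-seq datasets. Computes
    Seurat-dialect differential-expression metrics (avg_log2FC, pct.1, pct.2,
    diff_pct, adjusted Wilcoxon p-values), converts them into per-marker
    information-entropy profiles ranked across datasets, screens markers with
    dispersed positive-cell distributions on 2-D embeddings using local
    outlier factor scores, and validates marker panels by K-means regrouping
    of clusters and per-marker F1 scores against reference labels. Includes a
    negative-binomial multi-dataset simulator with planted markers of
    controlled quality (specific, diffuse, bimodal, unstable) for calibration
    and testing, and ships a curated catalog of human prostate cell-type
    markers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    irlba,
    uwot,
    FNN,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, GeneExpression, Software
RoxygenNote: 7.3.3
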