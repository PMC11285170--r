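Package: openanno
Title: Open-Set Cell-Type Annotation for Single-Cell Chromatin Accessibility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates cell types in single-cell chromatin accessibility
    (scATAC-seq) and scRNA-seq data by open-set domain adaptation: a shared
    variational autoencoder embeds labeled source and unlabeled target cells,
    a closed-set softmax classifier picks the nearest known type, and a bank
    of adversarially trained one-vs-all binary classifiers with per-class
    adaptive decision boundaries rejects cells of types absent from the
    training set as "unknown". Includes modality-specific preprocessing
    (binarization, prevalence filtering, highly variable feature selection,
    peak remapping), a synthetic-data generator with ground truth for
    benchmarking, and open-set evaluation metrics (effective assignment
    scores and Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
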