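Package: ontoAnnot
Title: Ontology-Corrected Multi-Label Cell-Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated cell-type annotation for single-cell RNA-seq with
    ontology-aware correction of gold-standard labels. Annotations are
    propagated along a curated cell-type graph (child-to-parent and synonym
    relations), turning single-label gold standards into multi-label ones so
    that datasets annotated at different granularity, or with synonymous
    label strings, stop contradicting each other. A fully connected
    multi-output neural network is trained on chunked expression data
    (softmax/cross-entropy for single-label gold standards, sigmoid/binary
    cross-entropy for propagated multi-label ones), and performance is
    measured per cell type with AUROC and AUPRC under cross-dataset
    cross-validation, which guards against the batch-effect-driven
    overestimation that cross-cell splits produce. A seeded synthetic-corpus
    generator with hierarchical cell types, annotation-granularity mismatch,
    synonymous labels and dataset batch effects makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    graphics,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
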