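Package: hubclass
Title: Network-Hub Gene Expression Classifiers for Tumor Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-score partial least squares (PLS) classifiers for
    two-class tumor versus non-tumor gene expression data from interaction
    network hub genes. Provides cross-dataset differential expression
    candidate selection with false discovery rate control, hub selection by
    connectivity and hidden-edge criteria on user-supplied interaction
    networks, ROC-derived decision thresholds, repeated random-split and
    k-fold cross-validation, hub/non-hub perturbation experiments that probe
    whether network topology drives classifier performance, exact 2x2
    association tests, immunohistochemistry composite scoring, and a
    scale-free network expression simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    optparse
Config/testthat/edition: 3
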