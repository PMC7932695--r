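Package: faidr
Title: Function Analysis of Intrinsically Disordered Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-instance statistical modelling of intrinsically
    disordered region (IDR) function. Proteins carry binary functional
    annotations while molecular-feature vectors are defined per IDR; which
    IDR in a multi-IDR protein carries the function is treated as a hidden
    variable and inferred by expectation-maximization wrapped around
    L1-penalized (elastic-net) logistic regression fitted by iteratively
    reweighted least squares. The package infers sparse feature-function
    associations, scores individual IDRs and whole proteins, extracts
    t-statistics from unpenalized refits and clusters them, evaluates
    predictions by cross-validation and held-out ROC/AUC, generates
    synthetic multiple-instance datasets with known ground truth, and
    computes single-sequence molecular features (isoelectric point,
    Kyte-Doolittle hydropathy, composition, motif counts) from protein or
    DNA sequences.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'faidr-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'model.R'
    'fit.R'
    'association.R'
    'seqfeatures.R'
    'catalog.R'
    'evaluation.R'
    'synthetic.R'
    'io.R'
    'cli.R'
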