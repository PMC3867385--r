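Package: sepsisPanel
Title: Biomarker Panel Discovery for Neonatal Sepsis via Canonical
    Correlation and Sparse Support Vector Machine Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies minimal panels of hematological biomarkers that
    discriminate septic from nonseptic neonatal sepsis evaluations.
    Exhaustive canonical-correlation subset selection ranks every
    combination of biomarkers against the sepsis label, and the selected
    panels are validated with a bagged 1-norm (sparse) linear support
    vector machine trained by linear programming with class-balanced
    slack costs, alongside a LASSO logistic regression comparator.
    Includes the hematologic 2-of-4 sepsis scoring rule, three-group
    outcome assignment, diagnostic performance measures, vertically
    averaged ROC curves, and a seeded synthetic cohort generator that
    emulates a neonatal intensive care unit dataset for end-to-end
    validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cca.R'
    'cohort.R'
    'labeling.R'
    'llr.R'
    'lp.R'
    'metrics.R'
    'pipeline.R'
    'sepsisPanel-package.R'
    'ssvm.R'
    'standardize.R'
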