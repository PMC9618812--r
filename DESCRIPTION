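Package: mirtree
Title: Blood miRNA Decision Trees for Chemo-Immunotherapy Response in B-CLL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse blood microRNA qPCR panels as predictors of
    complete remission with bone-marrow-undetectable minimal residual disease
    after FCR chemo-immunotherapy in B-cell chronic lymphocytic leukemia.
    Implements TaqMan low-density-array screening statistics (global-mean Ct
    normalisation, geometric-mean fold change, volcano categorisation with a
    detection-limit filter), Shapiro-Wilk-gated univariate comparisons,
    backward-selection logistic regression, ROC construction with
    Youden-index cutpoints, recursive decision-tree building by
    most-significant-variable splitting, Kaplan-Meier / log-rank / Cox and
    landmark survival analysis of the tree-defined prognostic groups, cohort
    response accounting with evaluable denominators, and a synthetic cohort
    generator with planted ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
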