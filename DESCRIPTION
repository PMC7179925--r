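Package: oncostage
Title: Tumor Stage Classification from RNA Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating tumor stage classifiers from
    bulk RNA-seq expression matrices (FPKM). Implements per-transcript
    directional threshold models ranked by AUROC, multi-method feature
    selection (fast correlation-based filtering on symmetrical uncertainty,
    ANOVA F ranking, L1-penalized linear-margin selection, and a stochastic
    subset search maximizing cross-validated MCC), RBF-kernel margin
    classifiers for binary and one-vs-rest multiclass stage prediction, a
    confusion-matrix metric suite with bootstrap AUROC confidence intervals
    and PPV/NPV threshold tables, feature-specific quantile normalization
    for cross-cohort harmonization, and a synthetic expression-data
    generator with planted stage-informative transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
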