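Package: ogttbench
Title: Benchmarking OGTT-Based Predictive Models of Progression to Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the systematic benchmarking of
    biomarker-combination models that predict progression to type 2
    diabetes from oral glucose tolerance test (OGTT) measurements,
    clinical risk factors, HbA1c, and serum metabolites. Provides
    exhaustive enumeration of candidate variable sets, a regularized
    least-squares classifier scored by repeated nested cross-validation,
    ROC/AUC inference with the F-index optimal cutoff, DeLong confidence
    intervals and paired tests for correlated ROC curves, positive
    false discovery rate q-values, and a synthetic cohort generator
    that emulates the correlation and effect-size structure of a
    Scandinavian prospective diabetes cohort so that every stage is
    testable without access to the original (non-public) data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
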