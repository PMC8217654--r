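Package: ftsvalid
Title: Diagnostic Validation Pipeline for the Family Togetherness Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the quantitative validation methodology for the
    Family Togetherness Scale (FTS), a 30-item screener of family
    relational distress. Builds a triangulated criterion reference from
    community-leader ratings, family self-ratings, and consensus clinical
    GARF scores; screens candidate questionnaire items by Goldberg
    gradient scores and cross-validated permutation variable importance;
    scores the final scale on a 0-30 metric; and estimates diagnostic
    validity (equal-sensitivity/specificity cutpoints, AUC and exact
    binomial confidence intervals, standardized alpha, cross-reporter
    correlations). Includes a synthetic multi-informant cohort generator
    so every stage is testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
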