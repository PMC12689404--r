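Package: mirsig
Title: Cross-Species miRNA Biomarker Panels from Small Temporal Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving and validating compact circulating microRNA
    signatures across species. Implements per-feature linear modelling of a
    two-group by two-timepoint design with empirical-Bayes variance
    moderation, a global permutation test on sums of squared t-statistics,
    stability selection with elastic-net logistic models over small
    subsamples, cross-species miRNA name and seed-sequence harmonization,
    and composite z-score signature scoring with permutation-validated ROC
    analysis in independent cohorts. Includes synthetic-data generators that
    emulate the serum microarray and exosome count data structures the
    workflow targets, so every stage can be exercised and calibrated without
    access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
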