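Package: robdiv
Title: Informative Value of Risk-of-Bias and Reporting-Quality Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing risk-of-bias (RoB) and reporting-quality (RQ)
    assessments of the primary studies included in a systematic review. Provides
    a merged 48-item assessment instrument combining ARRIVE, CONSORT, SYRCLE and
    Cochrane items, validated ingestion of long- or wide-format score tables,
    irrelevant-aware per-item summaries, the distinctive informative value (DIV)
    statistic and item rankings, stratified chi-square comparisons across study
    types, reporting heatmap and RoB traffic-light plot builders, rule-based
    recommendations for partial assessment strategies with a Monte-Carlo
    evaluator, and a calibrated synthetic-corpus generator for testing the whole
    pipeline without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
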