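Package: palmcohort
Title: Subgroup Discovery for Social Support and Mental Distress with
    Partially Additive Linear Model Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based recursive partitioning (MOB) and partially additive
    linear model (PALM) trees for discovering sociodemographic subgroups in
    which the association between low social support (SSQN score of the
    Social Support Questionnaire) and mental distress (DASS-21) differs.
    Includes a calibrated synthetic retiree-cohort generator with planted
    subgroup effects and realistic missingness, DASS-21 and SSQ scale
    scoring with psychometric summaries, chained-equations imputation with
    predictive mean matching, score-based parameter instability tests, and
    an end-to-end analysis pipeline producing subgroup estimate tables and
    tree exports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
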