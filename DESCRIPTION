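Package: absolex
Title: Absolutist-Language Lexicon Scoring and Nested Group Inference for
    Online Forum Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores plain-text member documents from nested internet-forum
    corpora (members within forums within groups) against closed-vocabulary
    lexicons, with negation-, qualifier- and salutation-aware false-positive
    correction of the absolutist index. Compares groups with a word-count
    weighted multilevel mixed-effects model on log10(x+1) transformed indices,
    pairwise contrasts with Cohen's d, analysis of covariance, stratified
    bias-corrected and accelerated (BCa) bootstrap confidence intervals, and
    leave-one-forum-out sensitivity analysis. Includes per-word index
    matrices with principal-axis factor analysis (direct oblimin rotation)
    and a one-factor confirmatory measurement model, judge-panel vote
    aggregation for dictionary validation, and a synthetic corpus generator
    with known truth for end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    stringi,
    tibble,
    utils,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
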