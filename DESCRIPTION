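Package: guardnet
Title: Guarding, Pain and Emotion: Rater Aggregation, Reliability and
    Gaussian Bayesian Networks for Chronic-Pain Movement Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for observer-rated guarding behaviour in
    chronic low-back-pain patients: a synthetic cohort generator emulating
    multi-rater physiotherapist annotation of exercise instances, rater
    aggregation (guarding sum scores, self-efficacy medians), one-way
    random average-measures intraclass correlation, Spearman correlation
    and dichotomization summaries, and linear-Gaussian Bayesian-network
    structure learning (BIC-scored hill climbing, exhaustive search,
    Fisher-z conditional-independence tests, Grow-Shrink and IAMB Markov
    blanket discovery) with arc strengths and cross-validated prediction
    of guarding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
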