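Package: eapipe
Title: Empathic Accuracy Scoring and Moderated Multilevel Inference for
    Dyadic Rating Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for empathic-accuracy (EA) analysis of
    continuous dyadic affect-rating streams, as used in placebo-controlled
    alcohol-administration designs: 5-second interval binning with edge
    truncation, autoregressive (Yule-Walker) handling of serial dependence,
    per-clip perceiver-target correlations with Fisher z transformation, and
    moderated linear mixed models with containment degrees of freedom, simple
    slopes at +/- 1 SD of a continuous moderator, and Cohen's d effect sizes
    derived from F and t statistics. Includes a seeded synthetic-dyad
    generator with known ground-truth effect structure so every stage of the
    pipeline is testable without access to raw study data, plus AUDIT
    questionnaire scoring, Cronbach's alpha, summary-statistic t tests, and a
    per-weight alcohol dose calculator.
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
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
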