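Package: altoscreen
Title: Scoring and Diagnostic-Accuracy Evaluation for the ALTO Alopecia
    Areata Screening Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the analysis pipeline for the Alopecia Areata
    Assessment Tool (ALTO), a self-administered eight-item screening
    questionnaire for alopecia areata. Provides the questionnaire data
    model with conditional (skip-logic) items, a boolean rule engine for
    the nine published scoring algorithms, diagnostic-accuracy summaries
    (sensitivity, specificity, PPV, NPV) with Clopper-Pearson exact
    binomial confidence intervals, reconstruction of integer confusion
    matrices from published rounded summary statistics, cohort
    comparison statistics (one-way ANOVA, Fisher's exact test,
    Sidak-adjusted pairwise contrasts), and a seeded synthetic-cohort
    generator that emulates the pilot study's response structure so the
    whole pipeline is reproducible without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
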