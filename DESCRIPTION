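Package: csinaming
Title: Typed Picture-Naming Experiments: Keystroke Processing,
    Automated Response Classification, and Cumulative Semantic
    Interference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running and analysing web-based typed
    picture-naming experiments in the cumulative semantic interference
    (CSI) paradigm.  Builds pseudorandomized stimulus lists under
    within-category lag constraints, parses keystroke logs, reconstructs
    backspace-corrected word entries, classifies response correctness
    automatically via the Jaro string distance (with Levenshtein and
    optimal-string-alignment variants) and accepted naming alternatives,
    computes five-character-word typing-test metrics, fits gamma
    generalized linear mixed models with identity link (and binomial
    error models) with a documented random-structure reduction ladder,
    produces Morey-adjusted within-subject summaries, and estimates
    statistical power by simulation.  A synthetic-experiment generator
    with planted ground-truth labels makes every stage of the pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmmTMB,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
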