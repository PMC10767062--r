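Package: musetrack
Title: Stimulus Reconstruction and Mixed-Model Analysis of Cortical
    Tracking of Music
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cortical tracking of continuous music
    stimuli with electroencephalography (EEG). Implements backward
    temporal-response-function stimulus reconstruction (lagged design
    matrices, closed-form ridge regression, nested leave-one-out
    cross-validation of the ridge parameter, Pearson reconstruction
    accuracy), equivalent-rectangular-bandwidth (ERB) cochleagram
    amplitude-envelope extraction, behavioral-indicator coding
    (familiarity, mind wandering, repetition), permutation null
    distributions, and group inference with linear mixed models with
    crossed Subject and Stimulus random intercepts, including stepwise
    backward model reduction with Satterthwaite tests. A synthetic-study
    generator with a known forward model makes every stage verifiable by
    parameter recovery.
License: MIT
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
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
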