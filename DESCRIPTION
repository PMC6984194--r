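Package: smrbci
Title: Self-Paced Sensorimotor-Rhythm Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for self-paced motor-imagery
    neurofeedback delivered through an embodiable robotic hand. Generates
    synthetic 24-channel sensorimotor-rhythm EEG with class-specific
    event-related desynchronization (ERD), trains common-spatial-pattern (CSP)
    log-variance features with regularized logistic classifiers, runs the
    six-state ensemble controller that turns streaming class probabilities
    into hand movements, and evaluates feasibility with Morlet time-frequency
    ERD measures, CSP quality scoring, block-wise cross-validated training
    accuracies, trial-based feedback accuracies, questionnaire construct
    scores, and bootstrap resampling statistics (mixed ANOVA, t-test,
    correlation) with Bonferroni-Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
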