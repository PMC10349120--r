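Package: betastate
Title: Beta-Distribution Learning and Hidden-State Inference for Aversive
    Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of Pavlovian aversive reversal-learning
    experiments in which participants rate the probability of an upcoming
    shock on every trial.  Implements a gradual one-state learner that
    maintains a single beta-distributed belief and an n-state extension that
    infers hidden contexts by tracking recency-weighted surprise, polling
    existing states and creating new ones under a Chinese-restaurant-process
    difficulty schedule.  Provides maximum-likelihood fitting of both models
    under a beta likelihood with multi-start derivative-free optimisation and
    BIC comparison, a constrained pseudo-random task-schedule generator with
    an explicit validator, model-free behavioural markers (trial-wise
    learning rates with meaningful/oddball classification, post-reversal
    slopes, stable-window means, error from the running reinforcement rate),
    a synthetic-cohort generator with a trait-anxiety covariate, and
    pipeline-level tools for model and parameter recovery, bootstrap and
    permutation correlations, split-half out-of-sample checks and a
    Fisher-z power calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
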