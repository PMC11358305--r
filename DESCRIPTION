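Package: revalr
Title: Simulation and Model-Based Analysis of Multi-Reward Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying experience-based and inference-based value
    updating in five-stimulus reversal-learning tasks. Simulates the NOVEL
    (per-session learning with one mid-session reversal) and FAMILIAR
    (criterion-triggered reversals between two known reward patterns) tasks
    as closed-loop environments; implements a Rescorla-Wagner softmax
    learner (EXP) and a mixture-of-softmax inference learner (INF) as
    generative agents and as likelihood models; fits parameters per session
    by multi-start maximum likelihood, with a variant that estimates a
    separate post-reversal learning rate; compares models via BIC posterior
    probabilities; and computes event-level behavioral statistics
    (phase-wise optimal-choice rates, experience-conditioned trials,
    inference trials, and the devaluation proportion-shifted index).
    Includes a synthetic-cohort generator with known ground truth for
    parameter-recovery and treatment-contrast studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    lhs,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
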