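Package: banditflex
Title: Behavioral Flexibility Analysis for Two-Choice Reversal and
    Water-Tube Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for avian behavioral-flexibility experiments
    built on trial-by-trial two-choice records: sequential
    proficiency-criterion detection (17-of-20 with per-10-trial-block
    sub-criteria), classification of learning strategies on a contextual
    binary bandit (epsilon-first versus epsilon-decreasing), exact two-tailed
    binomial preference tests with Bonferroni-Holm correction for
    object-choice (water-tube) experiments, reversal-learning flexibility
    scores, and tie-corrected Spearman rank correlations across contexts.
    Includes generators for epsilon-schedule bandit agents, pseudorandomized
    side sequences, and multi-choice water-tube sessions so the full pipeline
    is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
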