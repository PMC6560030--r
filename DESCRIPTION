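Package: futurestates
Title: Decoding Distal Future-State Representations During Goal-Directed
    Learning with fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for asking whether multivoxel fMRI patterns
    evoked at the start of a multi-step maze come to carry information about
    the distal state the learner will only see tens of seconds later.
    Provides a synthetic-data generator for the Y-maze learning and localizer
    designs (event tables, behavior, voxel patterns, and BOLD with a known
    planted future-state signal), single-event (least-squares-all) GLM
    estimation, pairwise linear support-vector classifiers trained on
    localizer patterns and applied across task phases to yield bounded
    decision values, regressions of state-1 decision values on current-state,
    future-state and correct-repetition predictors with group inference,
    equivalence (TOST) and power calculators, a simplified ROI-timecourse
    psychophysiological interaction, and an orchestration layer that runs the
    whole analysis end-to-end for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
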