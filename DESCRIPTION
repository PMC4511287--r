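Package: boldgate
Title: Block-Design BOLD Deactivation Analysis with Antagonism Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting unidirectional task-induced BOLD deactivation
    in block-design fMRI. Builds experiment timelines and GLM design matrices
    with a canonical double-gamma haemodynamic response, runs mass-univariate
    ordinary-least-squares fits with motion nuisance regressors and contrasts
    against the pooled rest baseline, computes random-effects group maps,
    calibrates minimum cluster extents by Monte-Carlo simulation, and
    summarises whole-mask t-value distributions into significant-voxel counts
    and an antagonism index that separates "antagonistic" (push-pull) from
    "gating" (deactivation-only) response regimes. A synthetic-data module
    generates BOLD runs with known ground truth, Likert questionnaire tables
    with a condition-dependent Thoughts-Sensations correlation, and
    quasi-periodic respiration traces, so the full chain is testable end to
    end without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
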