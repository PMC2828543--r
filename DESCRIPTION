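Package: satlearn
Title: Simulation and Analysis of the Salience Attribution Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing the Salience Attribution
    Test (SAT), a probabilistic reward learning game with compound cues
    varying on a task-relevant and a task-irrelevant visual dimension.
    Provides the task engine (trial schedules, per-subject reaction-time
    calibration, the reward-scaling payout rule), synthetic subjects built
    on a Rescorla-Wagner feature learner with an aberrant-salience bias,
    the behavioural learning measures (explicit and implicit, adaptive and
    aberrant) with outlier exclusion and earnings summaries, a first-level
    fMRI GLM with a double-gamma haemodynamic basis, cosine drift terms and
    AR(1) prewhitening including the per-block subjective relabelling that
    defines the aberrant reward-prediction contrast, and group-level
    covariate analysis with spherical volumes of interest and max-statistic
    permutation correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
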