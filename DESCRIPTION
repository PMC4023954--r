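Package: momentumdyn
Title: Team Psychological and Behavioral Dynamics During Momentum Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dyadic ergometer-rowing sessions in which a
    displayed time gap to a virtual opponent is scaled stepwise to induce
    positive or negative team momentum. Provides momentum time-gap schedules,
    a synthetic session generator with coupled oscillatory kinematics,
    stroke-locked force pulses and 9-point psychological item responses,
    continuous relative phase of the dyad via the analytic signal,
    sectioned aggregation of force, relative phase and team-mean item scores
    by time gap, and within-team Monte Carlo permutation inference (trend,
    trend-difference, pairwise-gap and combined coordination tests) with
    team-averaged Cohen's d effect sizes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
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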