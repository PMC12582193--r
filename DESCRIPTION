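Package: tcfsim
Title: Simulation and Analysis of Tracking Continuous Flash Suppression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing tracking continuous flash
    suppression (tCFS) experiments with moving dot stimuli. Generates
    point-light walker animations and their classic manipulations
    (inversion, spatial and temporal scrambling, speed scaling, radial
    optic flow), synthesises Mondrian mask sequences with controlled RMS
    contrast, runs the tCFS contrast-tracking trial state machine against
    configurable stochastic observers, and recovers suppression depth
    through the standard analysis pipeline: participant screening,
    threshold aggregation, within-participant error correction,
    repeated-measures ANOVA with partial eta squared, and
    Bonferroni-corrected post hoc comparisons with Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
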