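Package: prospectime
Title: Analysis of Prospective Verbal Time Estimation Under Cognitive and Motor Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for prospective verbal duration-estimation
    experiments in which participants judge intervals of tens of seconds to minutes
    while performing concurrent cognitive tasks (fixating, reading, mental arithmetic)
    in different motor conditions (sitting, treadmill walking). Provides a synthetic
    trial generator with a linear internal-clock model and a pacemaker-accumulator
    (attentional gate) model, robust estimation utilities (Hodges-Lehmann pseudomedian,
    pseudomedian-centred outlier filtering, bootstrap variance propagated through the
    filtering stage, exact one-sample Wilcoxon signed-rank tests, slope z-tests), and
    an analysis chain that bins estimation biases over short duration windows, fits
    weighted linear models with chi-square goodness of fit, quantifies scalar timing
    via coefficients of variation, and summarises motor and cognitive effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
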