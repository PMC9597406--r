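Package: gaitccp
Title: Competing-Cost-Pair Analysis of Muscle Activation and Metabolic
    Cost in Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the trade-off between whole-body metabolic
    power and fatigue-like muscle activation costs during walking. Processes
    surface electromyography into linear envelopes and per-stride activation
    rates, detects strides from vertical ground reaction force by relative
    thresholding, computes steady-state mass-specific metabolic power from
    breath-by-breath gas exchange, and evaluates weighted activation cost
    functionals (mean squared activation, min-max, muscle-volume-weighted).
    Includes a competing-cost-pair (CCP) analysis of crouch versus incline
    walking choices, a condition-comparison statistical decision tree, and a
    synthetic gait-trial generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
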