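Package: itclab
Title: Adaptive Intertemporal-Choice Staircase Tasks and Hyperbolic
    Discounting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for intertemporal-choice (ITC)
    experiments with adaptive staircase titration. Implements the staircase
    task engine (12 arms: 6 delays x 2 initial delayed rewards, 5 titration
    steps, 3 blocks), hyperbolic subjective value with a softmax choice rule,
    individual-level maximum-likelihood estimation of the discount rate k and
    inverse temperature mu with multi-start diagnostics and uniqueness
    checks, the cognitive intervention task logic (associative memory
    schedules, Serial-7s working-memory validator, spatial attention scorer),
    a synthetic cohort generator with known ground truth, and the group-level
    statistics: pre/post effect measures, MAD outlier exclusion, bootstrap
    t-tests and correlation tests, mixed-design ANOVA, sliding-window
    learning curves, and binned performance-effect associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
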