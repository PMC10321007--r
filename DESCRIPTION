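Package: orgssm
Title: State-Space Modelling of Directional Organelle Movement
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of directional movement of organelles or
    cells from tracked time-lapse trajectories. Estimates movement start
    times with three detectors (a Bayesian state-space model with a
    time-varying stimulus coefficient, a Kalman-filter state-space variant,
    and a model-free heuristic on raw distances), infers intracellular
    signal-transfer speed and movement kinetics by repeated-median robust
    regression and pairwise comparison, and estimates per-cell common
    dynamics with a hierarchical state-space model. Includes a trajectory
    simulator with known ground truth and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
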