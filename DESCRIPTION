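Package: thermalsoar
Title: Thermal Soaring Flight Simulation, Reinforcement Learning and
    Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A vulture-inspired thermal soaring toolkit: a point-mass glider
    simulator coupled to a drifting-thermal atmospheric model, an episodic
    reinforcement-learning environment with shaped rewards (climb rate,
    centering and stability penalties) and curriculum training of a
    deterministic-policy-gradient actor-critic agent, a soaring-efficiency
    metric bounded by algebraic baseline and optimal steady-circle climb-rate
    solvers, kinematic estimators for bank angle, wind and thermalling
    diameter applicable to 1 Hz bird-style GPS tracks, and k-means clustering
    of hidden-layer network activations with knee-based model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
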