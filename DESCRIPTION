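Package: anklewalker
Title: Ankle-Actuated Bipedal Walking Model with Entrainment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a one-degree-of-freedom,
    state-determined model of bipedal walking: a point mass on massless legs
    with a pre-loaded torsional ankle spring released at heel strike, hybrid
    double-stance (four-bar linkage) and single-stance (inverted pendulum)
    dynamics, and inelastic foot-ground collisions. Provides event-driven
    simulation of steps and multi-step walks with ground-reaction-force and
    energy monitors, the closed-form step-to-step (Poincare) map with its
    fixed point and Floquet stability analysis, critical-stiffness and gait
    feasibility checks, and experiments on entrainment and phase locking of
    the gait to periodic plantar-flexion torque pulses, including basin-of-
    entrainment scans and speed-versus-pulse-phase curves. Results are tidy
    tibbles with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
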