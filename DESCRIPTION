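Package: stwsim
Title: Predictive Reflex-Controlled Sit-to-Walk Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-dynamic predictive simulation of the sit-to-walk movement
    with a planar neuromusculoskeletal model: an 11 degree-of-freedom articulated
    rigid-body plant actuated by 20 Hill-type muscle-tendon units, Hunt-Crossley
    compliant chair and ground contact, a two-state reflex standing-up controller
    followed by a reflex gait controller, and CMA-ES optimization of the
    controller parameters against a composite movement objective (gait velocity,
    joint-range and knee-limit penalties, head acceleration, metabolic energy,
    cubed activations, trunk torque, and an optional knee-load pain-avoidance
    cost). Includes condition sweeps for bilateral vasti weakness and for
    stepping-knee peak-load thresholds, movement-event detection, joint-load and
    trunk-flexion measures, and writers for CSV and OpenSim storage files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
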