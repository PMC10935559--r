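Package: pftwin
Title: Patellofemoral Digital Twin: Rigid-Body Contact Simulation of
    Patellar Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rigid-body multibody simulation of the patellofemoral joint for
    patellar-tracking analysis and treatment prediction. Provides a synthetic
    sensorized knee test bench (trochlear-groove surface with an analytic
    ground truth, icosphere patellar button, virtual optical markers), two
    interchangeable collision-detection backends (AABB-tree mesh-to-mesh and
    an analytic sphere-versus-fitted-polynomial-surface formulation), the
    Flores dissipative normal contact model, linear spring-damper tendons,
    augmented-Lagrangian Newmark integration with velocity and acceleration
    projections, static-equilibrium initialization, marker filtering and pose
    reconstruction, validation metrics, and genetic-algorithm identification
    of tendon parameters for simulating tibial tuberosity medialization.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
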