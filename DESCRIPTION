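Package: hillfuse
Title: Fused Electromyography and Ultrasound Driven Hill-Type Neuromuscular
    Model of Ankle Plantarflexion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calibratable Hill-type neuromuscular model of the ankle
    plantarflexors (lateral gastrocnemius and soleus) that predicts the net
    plantarflexion moment over the walking stance phase from surface
    electromyography (sEMG) and ultrasound-measured muscle thickness. Muscle
    activation is a convex fusion of an sEMG-derived component (second-order
    recursive neural-activation filter plus nonlinear shaping) and an
    ultrasound-derived component (normalized muscle-thickness excursion). A
    two-segment geometry model, a piecewise tendon force-strain law, and
    Hill-type force-length-velocity curves are closed by a per-sample
    tendon-muscle equilibrium solve. Model parameters (shape factor, tendon
    slack length, maximal contraction force, allocation gain per muscle) are
    identified by bounded Levenberg-Marquardt least squares against inverse
    dynamics benchmark moments, in single-speed or inter-speed mode. Includes
    signal preprocessing (zero-phase Butterworth filtering, envelope
    extraction, stance segmentation from vertical ground reaction force), a
    multi-speed synthetic gait-trial generator with known ground truth,
    accuracy metrics (RMSE, normalized RMSE, R squared) and per-cycle
    correlation analysis with Fisher aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
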