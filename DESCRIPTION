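Package: apahtp
Title: Alternating-Projections SAR Optimization for Microwave Hyperthermia
    Treatment Planning
Version: 0.1.0
Authors@R: person("APA-HTP", "Developers", role = c("aut", "cre"),
    email = "apahtp@example.org")
Description: Deterministic specific-absorption-rate (SAR) based treatment
    planning for phased-array microwave hyperthermia. Implements the
    alternating projections algorithm (APA) with a two-level power mask,
    an adaptive Gaussian threshold search with Pareto knee selection,
    the planning metrics HTQ and Vchi%H, a particle swarm optimization
    benchmark, a surrogate near-field generator for a layered cylindrical
    phantom, and a steady-state Pennes bioheat solver with thermal dose
    estimators (T90/T50/T10) and input-power calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
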