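Package: cryosim
Title: Multi-Probe Cryoablation Simulation with Phase Change and Damage Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transient three-dimensional (and axisymmetric) finite-volume solver
    for the Pennes bioheat equation with liquid/mushy/solid phase change handled
    by the effective heat capacity method, threshold/time thermal damage
    kinetics, cryoprobe layout generation (single, five, seven, nine probe
    patterns), ice-ball isotherm morphometrics (extents, volumes, warm zones,
    merge tracking), analytic verification oracles (two-phase Neumann/Stefan
    front, lumped perfusion relaxation, grid-convergence harness), YAML
    configuration with scenario presets, and VTK/CSV/JSON result export.
    Intended for preoperative planning studies of percutaneous cryoablation
    probe layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
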