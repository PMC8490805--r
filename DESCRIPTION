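Package: porterflow
Title: Two-Stage State and Rate-Parameter Estimation for Hospital Patient-Flow Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compiles rule-based hospital patient-flow networks into linear
    compartmental dynamics, estimates and forecasts the flow state with a
    continuous-discrete Kalman filter over sensitivity-augmented dynamics, and
    recursively estimates rate-parameter perturbations by forgetting-factor
    least squares with Fisher-information propagation.  Includes a seeded
    discrete-event simulator of a hospital porter dispatch service (order
    arrival, porter search, walking and patient migration stages) calibrated
    by lognormal moment matching, plus CSV/YAML input-output and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
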