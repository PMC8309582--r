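Package: stkrige
Title: Spatio-Temporal Kriging of Mobile Air-Quality Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping urban air pollution from networks of mobile
    low-cost sensors backed by one fixed reference station. Implements
    per-sensor linear calibration against the reference series, empirical
    spatio-temporal variography (omnidirectional and directional) with
    metric-anisotropy model fitting by bound-constrained quasi-Newton
    optimisation, three kriging predictors (simple kriging on residuals,
    ordinary kriging, and kriging with external drift) plus a
    spatio-temporal inverse-distance-weighting baseline, scenario-based
    cross-validation (random points, path segments, leave-route-out), and
    gridded prediction/variance map export. A synthetic campaign generator
    simulates tram-like trajectories over a latent Gaussian random field
    with a diurnal mean so the whole pipeline can be exercised and tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
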