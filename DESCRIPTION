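Package: gaitbac
Title: Estimating Blood Alcohol Content from Smartphone Gait Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating blood alcohol concentration (eBAC) from
    smartphone tandem-gait inertial signals. Computes eBAC trajectories from
    hourly self-reported drink counts via the Matthews-Miller formula,
    extracts a 24-dimensional sliding-window feature set (mean, standard
    deviation, inter-axis correlation, FFT energy) from tri-axial
    acceleration and attitude recordings, and fits a Bayesian-regularized
    neural network regressor trained by Levenberg-Marquardt with
    evidence-framework hyperparameter updates. Includes a synthetic-data
    generator emulating an ecological-momentary-assessment drinking study
    so the full pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
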