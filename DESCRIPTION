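Package: heatscope
Title: Conformal Prediction Intervals for Non-Invasive Core Body Temperature Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-invasive core body temperature (CBT) estimation
    with statistically calibrated uncertainty under heat stress. Implements a
    windowed hybrid sequence regressor (bidirectional LSTM over heart-rate and
    skin-temperature histories combined with a dense encoder over demographic
    and environmental context), output-stratified inductive conformal
    prediction (SCOPE) for finite-sample-valid prediction intervals, an
    extended-Kalman-filter heart-rate baseline, leakage-free grouped data
    partitioning with train-only scaling and k-nearest-neighbour imputation,
    coverage-curve evaluation, session-level interval fine-tuning, and a
    configurable four-state heat-strain alert engine. A synthetic multi-domain
    heat-stress cohort generator makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
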