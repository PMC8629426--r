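Package: icikin
Title: Tumor Response Kinetics Under Immune Checkpoint Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic modeling of solid-tumor burden trajectories under
    PD-1/PD-L1 checkpoint inhibitor therapy. Implements a closed-form
    normalized tumor-burden model governed by a tumor proliferation rate
    (alpha), an anti-tumor immune state (Lambda), and an
    immunotherapy-effect rate (mu), together with the inference pipeline
    around it: per-patient nonlinear least-squares parameter estimation
    from longitudinal lesion measurements, early-truncation stability
    analysis, RECIST-derived response classification and long-horizon
    projection, ROC/Youden threshold selection, mapping of fitted
    parameters to CD8+ T-cell density and PD-L1 positivity, and a seeded
    virtual-cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
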