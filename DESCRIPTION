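Package: rtdose
Title: Real-Time Dose Reconstruction and Coverage Forecasting for
    MR-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of a real-time dose reconstruction
    workflow for an MR-guided linear accelerator. Streams linac control
    points and motion samples, derives beam-on segments, reconstructs the
    delivered dose per segment under rigid or deformable anatomy updates,
    computes the planned dose to the same number of monitor units, and
    forecasts the end-of-fraction dose and target coverage (V95%).
    Includes synthetic phantoms (diode-array and deformable film setups),
    an analytic primary-beam dose engine with a Monte-Carlo-like noise
    model, a demons-style deformable registration stand-in with
    displacement-field algebra, gamma analysis, dose-deviation metrics,
    and a simulated real-time session runner with timing and duty-cycle
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
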