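Package: ra223spect
Title: Desk-Scale Simulation and Semi-Quantitative Analysis of Ra-223 SPECT Phantom Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates planar and SPECT acquisitions of digital Ra-223
    phantoms under collimator- and energy-window-dependent detection
    models, reconstructs SPECT volumes with OSEM and Butterworth
    post-filtering, and computes the semi-quantitative image-quality
    metrics used in Ra-223 feasibility work: hot-rod-to-background ratio
    (HBR), contrast-to-noise ratio (CNR), sphere-to-background ratio
    (SBR), lesion-to-background ratio (LBR), isocontour-VOI threshold
    calibration and count linearity, together with the matching
    nonparametric statistical battery (exact Wilcoxon signed-rank,
    Friedman, Steel-Dwass all-pairs, paired t, Pearson regression).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
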