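Package: oisr
Title: Optical Intrinsic Signal Imaging Analysis of Evoked Cerebral
    Blood Volume and Pial Artery Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-evoked optical intrinsic
    signal (OIS) imaging of the cortical surface at the 570 nm hemoglobin
    isosbestic wavelength. Converts repeated-trial reflectance movies into
    percent cerebral-blood-volume (CBV) change maps, extracts maximum
    response, time-to-peak and activation extent from an automatically
    selected region of interest, segments pial vessels with a trainable
    multi-scale random-forest pixel classifier, derives the responsive
    area from a temporal standard-deviation map (mean + 2 SD threshold),
    decomposes the field of view into responsive artery, responsive
    tissue and non-responsive vessel regions, quantifies pial-artery
    dilation by pixel counting, and compares groups with Mann-Whitney,
    t-test and one-way ANOVA with Fisher LSD post-hoc tests. Includes a
    synthetic OIS movie generator with known ground truth (vessel
    geometry, hemodynamic response, artery dilation, physiological noise)
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
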