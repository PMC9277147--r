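Package: bevcine
Title: Predictive Beam's-Eye-View Cine Simulation for MR-Guided
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation of a predictive beam's-eye-view (BEV)
    2D-cine strategy for MR-guided radiotherapy of mobile thoracic
    tumors. A synthetic 4D breathing-thorax phantom generates
    time-resolved volumetric image series with controllable respiratory
    hysteresis; diaphragm waveforms are extracted by a navigator-box
    gradient method and b-spline resampled to cine frame rates;
    sliding-window autoregressive and LSTM forecasters predict the
    diaphragm position for the next cine frame; direction-resolved
    (inhalation/exhalation) motion libraries supply a motion-matched
    tumor volume, which is projected orthographically onto the BEV plane
    for fixed-field (IMRT) and rotating (VMAT) beam schedules; and
    beam-to-tumor conformality is verified with center-of-mass
    differences and Dice overlap against the phantom ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    RNifti,
    stats,
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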