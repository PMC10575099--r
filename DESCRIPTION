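Package: aquavital
Title: Wearable Bioimpedance Monitoring and Fuzzy Health Assessment for Live Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for assessing the vitality of live fish kept
    under waterless, low-temperature transport conditions from wearable
    multifrequency bioimpedance (WBIA) sweeps.  Converts raw real/imaginary
    sweep readings to calibrated impedance and phase, removes gross errors
    with a t-based (Romanovsky) criterion, smooths with Savitzky-Golay
    filtering, completes sparse biomarker checkpoints with natural cubic
    splines, screens stress-related impedance/phase features by the maximal
    information coefficient (MIC), allocates per-biomarker stress weights by
    grey relational analysis (GRA), forecasts glucose, lactate and cortisol
    trajectories with a CNN-LSTM model whose residuals are rectified by an
    attention-augmented bidirectional GRU, and maps weighted total stress
    through a Z-shaped fuzzy membership function to a five-level health
    classification.  Includes a seeded synthetic-experiment generator with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
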