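Package: fullfield
Title: Ultra-Wide-Angle Visual Stimulation for fMRI: Geometry, Warping,
    Stimuli and Retinotopic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for presenting and analysing ultra-wide-angle (~175
    degree) visual stimulation in the MRI scanner bore. Models the optics of
    a tilted cylindrical projection screen viewed at close range, including a
    ray-traced projector model and a calibration-driven image warp that
    "wallpapers" a rectangular canvas onto the curved screen. Generates the
    stimulus classes used in wide-field retinotopy and scene-perception
    experiments (eccentricity-ring checkerboards, phase-scrambled scenes,
    postcard rescaling, central artificial scotomas, eccentricity-scaled item
    arrays with luminance matching), builds constrained fMRI block designs
    with one-back targets and BIDS-style event tables, and provides a
    first-level GLM with AR(1) prewhitening, percent-signal-change scaling,
    temporal SNR maps, conjunction-based region-of-interest logic and
    winner-take-all eccentricity preference maps. A synthetic-data module
    simulates calibrations, stimulus content and BOLD time series with
    planted tuning so that the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
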