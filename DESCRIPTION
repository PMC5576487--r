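Package: saccsupp
Title: Deconvolution and Permutation Statistics for Saccade-Related
    Suppression of Visual Cortical Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting cortical high-frequency broadband (HFB,
    70-150 Hz) responses to small saccades with responses to matched external
    stimulus displacements in intracranial EEG. Implements finite impulse
    response (FIR) deconvolution of overlapping event-related HFB transients
    by ordinary least squares, a within-electrode cluster-area label-shuffle
    permutation contrast, region-of-interest aggregation with between-subject
    error, saccadic and blink suppression indices, a Sorensen-Dice overlap
    permutation test, and a bias-corrected outlier-removal correlation
    randomization. Includes eye-event processing (pixel-to-degree geometry,
    velocity-threshold saccade detection, magnitude-matched saccade
    selection, gaze-validity rejection masks), HFB envelope estimation from
    raw traces, and a fully parameterised synthetic-data generator with known
    ground truth so the entire pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    jsonlite,
    methods,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
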