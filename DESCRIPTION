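Package: cohnet
Title: Coherence-Based EEG Functional Networks and Treatment-Outcome
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building weighted functional brain networks from
    multichannel EEG and relating their topology to clinical outcome.
    Covers synthetic cohort simulation with planted coherence structure,
    preprocessing (zero-phase band-pass filtering, average referencing,
    ICA plus discrete-wavelet suppression of ocular artifacts, fixed-length
    segmentation with amplitude-based rejection), magnitude-squared
    coherence via Welch auto- and cross-spectra, weighted graph metrics
    (clustering coefficient, local and global efficiency, characteristic
    path length), normality-gated group comparison with edge-wise
    false-discovery-rate correction, and leave-one-out cross-validated
    linear regression of symptom change ratios on network-property changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
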