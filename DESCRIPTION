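Package: cmconn
Title: Corticomuscular Connectivity Analysis for EEG and Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for estimating corticomuscular connectivity between
    electroencephalography (EEG) and surface electromyography (sEMG)
    recordings during trial-structured object-manipulation tasks.
    Implements signal conditioning (common average reference, zero-phase
    Butterworth band-pass and notch filtering, polyphase resampling,
    threshold-based trial rejection), event-related desynchronization
    maps (Morlet wavelet with bootstrap-t significance masks), sEMG RMS
    activation envelopes, power-based connectivity (Welch spectral
    feature vectors matched in length across modalities and compared by
    Spearman rank correlation), sliding-window histogram mutual
    information, and surface-contact group comparisons built on ANOVA
    with Bonferroni-corrected post-hoc tests. A synthetic session
    generator with known coupling gains and desynchronization depth
    provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
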