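Package: eegartifacts
Title: EEG Artifact Detection with a Dual-Domain Local-Global Feature
    Fusion Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies electroencephalography (EEG) artifacts
    (eye movement, blink, chewing, rhythmic chewing, muscle, electrode and
    shiver activity) from single-channel segments using a dual-branch
    convolutional/transformer network that fuses shallow local, deep local
    and global features extracted from the raw waveform and from its
    short-time Fourier transform spectrogram. Includes the full signal
    conditioning pipeline (rational polyphase resampling to 250 Hz,
    Butterworth band-pass, 50 Hz notch, annotation-driven segment
    extraction), a labeled synthetic artifact generator for end-to-end
    testing without clinical data, a deterministic Adam training loop with
    stratified five-fold cross-validation, per-class evaluation metrics,
    EDF input support and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
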