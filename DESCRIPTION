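Package: tfemi
Title: Motor-Imagery Detection from Short-Term Entropy of Time-Frequency
    Representations of EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting sensorimotor-rhythm motor imagery in
    multichannel EEG. Implements Cohen's-class time-frequency
    representations (spectrogram, Gabor, pseudo Wigner-Ville, smoothed
    pseudo Wigner-Ville) and their reassigned variants, short-term Renyi
    and Shannon entropy features computed on sliding windows, and
    time-resolved decoding with a shrinkage-regularized linear
    discriminant classifier. Includes a standard EEG preprocessing chain
    (zero-phase Butterworth filtering, resampling, epoching, amplitude
    based trial rejection, EOG regression, channel selection), a
    synthetic generator of motor-imagery paradigm recordings with
    controllable event-related desynchronization, movement-related slow
    potentials and time-frequency complexity effects, readers for EDF
    and BrainVision recordings, and a config-driven pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
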