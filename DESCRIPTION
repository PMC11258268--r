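Package: consonance
Title: Psychoacoustic Consonance Models for Continuous Intervallic Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling the perceived consonance of musical chords
    as a continuous function of pitch interval and timbre. Implements
    additive synthesis of harmonic, stretched, and gamelan-style
    (bonang) tone spectra; the Hutchinson-Knopoff interference model and
    a revised variant with a slow-beat pleasantness kernel and tunable
    amplitude exponent; pitch-class-spectrum harmonicity models
    (template cosine similarity, Kullback-Leibler pitch-clarity and
    max-peak statistics); a composite consonance model; Gaussian kernel
    smoothing of dense-rating data with participant-level bootstrap
    confidence bands; a derivative-based peak-picking algorithm with
    bootstrap peak reliability; a peak-Jaccard model-fitting objective
    with gradient-free optimization; simulation of dense-rating raters
    and Gibbs-Sampling-with-People chains; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
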