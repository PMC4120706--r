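Package: formantcomp
Title: Formant-Competitor Stimulus Construction, Synthesis, and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building dichotic speech-analogue stimuli in the
    second-formant-competitor (F2C) paradigm used to study informational
    masking of speech by extraneous formants. Implements depth scaling of
    formant-frequency contours about their geometric mean on a log scale,
    spectrally inverted and band-limited triangle-wave competitor contours
    matched in rate and depth to a target second formant, parallel-formant
    synthesis from a glottal-pulse source through time-varying second-order
    resonators, experiment condition tables with counterbalanced sentence
    rotation, keyword and phoneme intelligibility scoring, competitor
    efficacy, and Weibull psychometric-function fitting. A synthetic
    formant-track generator and simulated-listener module make the whole
    pipeline testable without recorded speech.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
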