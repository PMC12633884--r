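Package: pairtap
Title: Coupled-Oscillator Simulation and Stimulus Pipeline for Paired
    Synchronized Tapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation of a stochastic coupled phase-oscillator
    model of paired synchronized tapping, with discrete phase/period resets at
    each partner tap. Generates "humanized" (HUM), asynchrony-shuffled
    "randomized" (RAN) and near-isochronous (ISO) drum-tapping stimulus sets
    via ensemble selection on windowed detrended cross-correlation (WDCC)
    profiles; exports stimuli as standard MIDI and stereo WAV files with 4 to 1
    amplitude panning; and provides trial scheduling, participant screening
    and signal-detection (d-prime, criterion C) scoring for listening
    experiments on those stimuli.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
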