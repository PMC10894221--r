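Package: oscsense
Title: Coupled Relaxation-Oscillator Sensory Networks with a Winner-Take-All Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale software twin of a capacitively coupled VO2
    relaxation-oscillator sensory system. Provides a hysteretic
    threshold-switch compact model, an event-aware ODE simulator for
    capacitively coupled oscillator networks that encode capacitive
    sensor stimuli into phase-difference patterns, waveform analysis
    (peak timing, dominant frequency, synchronization, phase patterns,
    limit cycles), synthetic pressure/stretch sensor frontends, a
    mean-field winner-take-all decision network, and a FORCE-trained
    (recursive least squares) linear readout. Ships end-to-end touch,
    gesture and eight-mode classification experiments on synthetic
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
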