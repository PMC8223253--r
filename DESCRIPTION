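Package: scalpHFO
Title: Scalp EEG High-Frequency Oscillation Analysis for Infantile Spasms
Version: 0.1.0
Authors@R:
    person("EEG", "Methods Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of high-frequency oscillations (HFOs) on
    scalp electroencephalography: simulation of annotated multichannel EEG
    cohorts with 1/f background, sleep spindles, epileptiform discharges and
    injected oscillatory bursts; EDF reading and writing with average-reference
    and longitudinal-bipolar montages and zero-phase Butterworth band-pass
    filtering; envelope-based detection of gamma (40-80 Hz), ripple (80-200 Hz)
    and fast-ripple (200-300 Hz) events with cycle-count and regularity rules;
    Morlet-wavelet average band energy, responsible-lead and lobe summaries;
    BASED severity scoring and treatment-efficacy classification for infantile
    spasms; and aligned-rank-transform factorial ANOVA with Holm-corrected
    post hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
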