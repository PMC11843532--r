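Package: synflim
Title: Fluorescence-Lifetime Phasor Analysis of Amyloid Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-correlated single-photon-counting (TCSPC)
    fluorescence decays of molecular-rotor dyes during amyloid aggregation.
    Simulates periodic-excitation TCSPC histograms with instrument-response
    convolution and Poisson noise, fits mono- to tri-exponential reconvolution
    models and the amplitude-weighted mean lifetime, computes first-harmonic
    phasor coordinates with bootstrap uncertainties, classifies aggregation
    phasor trajectories against fibril and stabilized-oligomer reference sets
    by an error-bar overlap rule, and compares lifetime-onset versus
    intensity-t50 aggregation kinetics across protein variants. Includes a
    synthetic-data generator for whole aggregation experiments with presets
    emulating wild-type-like, A30P-like and deltaP1-like alpha-synuclein
    phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
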