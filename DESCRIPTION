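Package: phasegate
Title: Phase Opposition and Phase-Gated Connectivity Analysis for
    Trial-Locked Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the pre-movement oscillatory phase of trial-epoched neural
    signals (LFP/EEG) to trial-wise behavioural outcomes. Implements the phase
    opposition product with permutation and cluster-based family-wise error
    correction, spike-field phase-locking statistics, optimal-phase trial
    partitioning, phase-conditioned functional connectivity (debiased weighted
    phase-lag index) with lagged phase-coherence directionality, and individual
    alpha-peak estimation from 1/f-corrected spectra. Ships a synthetic-data
    generator that plants each effect (von Mises phase-coded trials on 1/f
    background, phase-modulated Poisson spiking, phase-gated lagged source
    pairs, subject cohorts with varying alpha peaks) so every analysis stage
    can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
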