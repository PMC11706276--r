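Package: navclamp
Title: Simulated Voltage Clamp and Dynamic Action Potential Clamp for
    NaV1.2 Channel Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical characterization of wild-type and mutant NaV1.2
    sodium channels entirely in silico. Provides Hodgkin-Huxley-style
    gating models parameterized from published per-variant measurements
    (peak current density, activation and inactivation midpoints,
    persistent-current fraction, recovery time constant), simulators for
    the standard whole-cell voltage-clamp protocols (peak IV, steady-state
    inactivation, paired-pulse recovery, persistent current), the
    corresponding analysis pipeline (conductance transform, Boltzmann and
    single-exponential fits, the 50-percent non-inactivating rule), a
    single-compartment axon-initial-segment hybrid neuron for dynamic
    action potential clamp experiments (input-output curves, sustained
    depolarization detection), and a synthetic-data generator with
    cell-to-cell variability and band-limited recording noise for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
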