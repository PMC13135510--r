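Package: netstates
Title: Dynamic Cortical Network States and Subcortical Coupling from
    Electrophysiological Recordings
Version: 0.1.0
Authors@R:
    person("Netstates", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers transient large-scale network states from multichannel
    electrophysiological recordings (cortical parcel channels plus a
    subcortical local field potential channel) with a time-delay embedded
    hidden Markov model, and characterises each state with state-weighted
    multitaper power and coherence spectra, beta-burst overlap, and
    permutation-based statistics.  Ships a synthetic-data generator that
    emulates Markov switching between band-limited oscillatory network
    states, state-dependent cortico-subcortical coupling, and a paired
    medication manipulation, so the whole pipeline is testable without
    access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
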