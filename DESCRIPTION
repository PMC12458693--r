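Package: watnet
Title: Grand Canonical Monte Carlo Water Networks and Free-Energy Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies binding-site water networks by grand canonical
    Monte Carlo (GCMC) sampling of rigid-water occupancy across an Adams
    B-value ladder, integrates the resulting titration curves into network
    binding free energies (grand canonical integration), clusters sampled
    water positions into hydration sites and scores them against
    crystallographic waters, runs dual-topology alchemical transformations
    with softcore potentials and an MBAR estimator, and assembles the legs
    into thermodynamic cycles with closure-error accounting.  Ships a
    synthetic cage-host generator and an exact grid grand-partition oracle so
    every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
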