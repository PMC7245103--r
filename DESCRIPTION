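Package: mobluesim
Title: Stochastic Self-Assembly of Molybdenum-Blue Clusters via
    Autocatalytic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic Monte Carlo (Gillespie) simulation of the
    self-assembly of giant polyoxomolybdate clusters such as the
    {Mo36} template, the {Mo132} Keplerate ball and the {Mo154}
    molybdenum-blue wheel. Enumerates coarse-grained nuclearity-based
    reaction networks with corner- and edge-bonded dimer lineages,
    templation and completion-bias rate rules, and simulates them
    exactly with a compiled direct-method stochastic simulation
    algorithm. Includes an analysis layer for critical transitions in
    the dimerization ratio, two-sided scaling-exponent fits,
    ball/wheel coexistence, lag-time and seeding experiments; a
    sigmoidal two-step autocatalytic (Finke-Watzky-type) kinetics
    module with a synthetic-trace generator; and a registry of the
    known cluster structures with formula-level oxidation-state
    bookkeeping.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
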