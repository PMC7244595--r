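Package: hemeqmc
Title: Multi-Orbital Anderson Impurity Modelling of Heme by Hirsch-Fye
    Quantum Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the magnetic electronic structure of heme
    groups with a five-orbital Anderson impurity model solved by Hirsch-Fye
    quantum Monte Carlo with discrete Hubbard-Stratonovich fields. Includes
    an exact-diagonalization oracle for small clusters, derived observables
    (effective magnetic moments, Curie-law susceptibility fits, chemical
    potential tuning, atomic magnetic-moment density maps, Fe-host spin
    correlations), a two-band model for temperature-dependent magnetic
    circular dichroism line shapes, inter-heme moment correlation algebra
    for the four-heme molecule, and synthetic generators that emulate
    DFT-derived parameter sets for deoxy- and oxy-heme clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
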