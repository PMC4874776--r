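Package: fgfilm
Title: Binding Isotherms and Mean-Field Modelling of Grafted FG-Nucleoporin Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of nuclear transport receptor (NTR) uptake by planar films
    of end-grafted FG-nucleoporin domains. Fits binding isotherms (Langmuir,
    Hill with negative cooperativity, low-concentration partition coefficients,
    master-curve collapse, FG-motif stoichiometry), solves a coarse-grained
    mean-field model of cohesive grafted bead-chains with absorbing spherical
    colloids in cylindrical geometry, reduces the resulting density fields to
    experimental observables (iso-density film thickness, bound-colloid areal
    densities), and calibrates the polymer-polymer and polymer-colloid contact
    energies against thickness and isotherm measurements. Includes a seeded
    synthetic-data generator emulating titration tables and a grand-canonical
    Monte Carlo oracle for validating the mean-field solver on small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
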