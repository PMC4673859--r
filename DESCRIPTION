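Package: surfdiff
Title: Surface-Dependent Diffusion and Reactions on Triangulated Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-particle stochastic simulator for membrane-bound molecules
    diffusing and reacting on triangulated surfaces, in which the diffusion
    coefficient of a species -- and the reaction parameters derived from it --
    depends on the surface a molecule currently occupies. Supports geodesic
    propagation of Brownian steps across panels, reflective boundaries,
    macroscopic-rate calibration of bimolecular binding radii, a plain-text
    configuration dialect with a surface_difc statement, built-in scenario
    generators (heterogeneous two-triangle plane, surface phosphorylation
    kinetics, receptor trapping at a postsynaptic-density-like microdomain),
    and trajectory analysis (mean square displacement, anomalous exponent,
    region enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
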