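Package: fret3wj
Title: Single-Molecule FRET and EMSA Analysis of RNA Three-Way Junction
    Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule FRET (smFRET) studies of
    RNA three-way junction geometry and protein-binding-driven conformer
    shifts, with electrophoretic mobility shift assay (EMSA) titration
    fitting. Converts two-channel donor/acceptor intensity trajectories into
    quality-controlled apparent-FRET traces via penalized change-point
    photobleach detection, fits Gaussian mixtures to time-binned FRET
    histograms, estimates conformer population fractions with bootstrap
    uncertainties and compares conditions by Welch t-tests, converts FRET
    efficiencies to inter-fluorophore distances through the Forster equation
    and ranks coaxial-stacking hypotheses against A-form helix contour
    lengths, and fits Hill binding isotherms to EMSA titrations with
    inverse-variance replicate combination. A synthetic-data generator
    produces ground-truth-labelled trajectories and titrations so every
    stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
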