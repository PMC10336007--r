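Package: chromcg
Title: Systematic Coarse-Graining of Chromatin Polymers from Contact Probability Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds fine-grained nucleosome-resolution bead-spring polymer
    ensembles constrained by a chromatin contact probability map (Micro-C/Hi-C
    style), using a two-step constraint-spring insertion scheme and an embedded
    Langevin dynamics engine. Measures scale-dependent coarse-grained
    observables (bead radius of gyration, bond length, overlap parameter,
    effective spring constant, bond and dihedral angle statistics and their
    effective potentials) and derives scale-dependent soft non-bonded pair
    potentials by iterative Boltzmann inversion with a parametric bounded
    soft-core form. Includes synthetic contact-map generation, ideal-chain /
    self-avoiding-walk / globule control ensembles, and map-similarity
    validation via a stratum-adjusted correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    minpack.lm,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
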