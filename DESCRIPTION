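Package: synDropSim
Title: Agent-Based Simulation and Analysis of Synthetic Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics of multivalent patchy particles
    with stochastic, detailed-balance dynamic bonding, inert crowders at a
    tunable effective temperature, and the analysis stack needed to study
    condensate assembly kinetics in silico: graph-based cluster statistics,
    cluster tracking and diffusivity, effective dissociation-constant and
    rate-constant estimation, and single-particle-track statistics (mean
    squared displacement, angle correlation, velocity autocorrelation).
    Models a two-component synthetic condensate system (a hexamer and a rod
    dimer with inducible heterodimerisation, "synDrops") together with
    ribosome-mimetic crowders and inert tracer nanoparticles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    xml2,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
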