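Package: kineticGC
Title: Agent-Based Simulation of Kinetic Selection in Germinal Centres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A stochastic, lattice-based agent model of the germinal centre
    reaction in which B-cell clones of identical affinity but different
    association/dissociation phenotypes compete for antigen presented by
    follicular dendritic cells. Affinity is defined on an abstract shape
    space and decomposed into per-time-step association and dissociation
    probabilities through a fixed per-clone angle; three antigen-collection
    mechanisms are supported (affinity-based capture, kinetic capture with
    probabilistic bond rupture during extraction, and kinetic capture
    without rupture). The package provides closed-form capture-probability
    oracles, a seeded replicate runner over a three-dimensional spherical
    lattice with chemokine fields and T-follicular-helper selection, and
    aggregation utilities for clonal dominance, output-cell production and
    affinity-maturation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
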