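Package: p53cg
Title: Coarse-Grained Simulation and Analysis of p53 Target-Search and
    Response-Element Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A residue-level coarse-grained model of the p53 tetramer
    searching for and recognizing DNA response elements. Builds one-bead
    per-residue protein topologies (structure-based Go potentials for
    folded domains, statistical local potentials for disordered tails,
    pairwise linker terms) and three-bead-per-nucleotide DNA duplexes,
    evaluates the composite energy with Debye-Hueckel electrostatics and
    excluded volume, propagates Langevin dynamics under constraints and a
    spherical container, runs replica-exchange umbrella sampling along a
    binding distance, and computes the derived observables: native-contact
    Q-scores, DNA bending scores, sequential-binding kinetics with
    exponential survival fits, potentials of mean force by WHAM,
    linker-connectivity typing and spatial occupancy grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
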