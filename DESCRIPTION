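Package: racerts
Title: Transition-State Conformer Ensembles by Constrained Distance Geometry
Version: 0.1.0
Authors@R:
    person("racerts", "maintainers", email = "racerts@example.org", role = c("aut", "cre"))
Description: Rapid generation of transition-state (TS) conformer ensembles from a
    single TS guess geometry. The reaction center and its immediate bonded
    neighbours ("frozen atoms") are held fixed while the remaining degrees of
    freedom are sampled by constrained distance-geometry embedding; conformers
    are refined with a classical force field under exact frozen-atom fixing,
    ranked by single-point energy, and pruned by an energy window and a
    heavy-atom RMSD criterion. Also provides the benchmark framework used to
    compare conformer generators: wall-time cost normalisation, combined
    reference-ensemble construction, Butina sphere-exclusion clustering,
    precision/recall/F1 space exploration, Jensen-Shannon space distribution,
    success rate, top-N accuracy, and Boltzmann-averaged activation-energy
    errors. Toy pentacoordinate SN2-like and square-planar organometallic
    transition states with brute-force enumerable rotamer inventories are
    generated programmatically so that the whole pipeline is testable without
    external data or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
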