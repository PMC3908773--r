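Package: FCCfold
Title: Evolutionary Search for HP-Model Protein Folding on the 3D FCC Lattice
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Protein structure prediction in the hydrophobic-polar (HP)
    model on the three-dimensional face-centered-cubic (FCC) lattice.
    Implements the lattice geometry (12 step directions, adjacency, the 17
    proper point-group rotations usable as direction-label permutations),
    conformation encoding and HH-contact energies, three local-search
    operators (rotation-based one-point crossover, a generalized pull move,
    and a K-site segment move with admissible lower-bound pruning), an
    elitist evolutionary algorithm combining them, an exhaustive
    self-avoiding-walk enumeration oracle for short chains, benchmark
    sequence collections, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, jsonlite, Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
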