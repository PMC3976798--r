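Package: spiralfold
Title: Multipoint Parallel Spiral Search for Lattice Protein Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio protein structure prediction on the three-dimensional
    face-centred-cubic (FCC) lattice. Conformations are self-avoiding walks over
    the 12-neighbour FCC lattice, scored either with the binary hydrophobic-polar
    (HP) contact energy or with the Berrera et al. (2003) 20x20 empirical
    residue-contact potential. The core optimiser is a hydrophobic-core-directed
    tabu local search ("spiral search") built from diagonal moves, pull-move
    random walks and relay-restarts, available in an HP-guided and a
    contact-matrix-guided variant. A multipoint parallel portfolio framework runs
    several guidance variants from different starting points in rounds, merging,
    deduplicating and reselecting the improving solutions between rounds.
    Evaluation utilities include relative improvement against energy lower bounds
    and superposition-free distance-matrix RMSD, plus benchmark protein fixtures,
    random instance generators, FASTA/HP input, JSON run reports and CA-trace PDB
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    bio3d,
    optparse
Config/testthat/edition: 3
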