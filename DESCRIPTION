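Package: rupee
Title: Purely Geometric Protein Structure Search with Run Position
    Encoded Torsion Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes protein backbones as sequences of torsion-angle and
    secondary-structure descriptors, shingles the sequences into
    run-position-encoded bags of hashes, and indexes the bags with
    min-hashing and locality-sensitive hashing (LSH) banding for fast,
    purely geometric structure search. Two search modes are provided: a
    fast mode ranking candidates by a longest-common-subsequence adjusted
    multiset Jaccard similarity, and a top-aligned mode that re-ranks the
    fast-mode shortlist by TM-score or RMSD using a built-in iterative
    TM-score alignment. Includes parsers for PDB and classic DSSP output,
    a synthetic fixture generator for descriptor sequences and idealized
    backbone coordinates, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
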