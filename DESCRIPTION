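Package: dnanma
Title: Normal Mode Analysis of Finite-Size DNA Nanostructures with
    Mass-Weighted and Symmetry-Reduced Elastic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse three-dimensional models of finite-size DNA
    nanostructure assemblies (2D tile rings and the 60-tile three-point-star
    buckyball cage), converts them into a mass-weighted chemical elastic
    network (lumped nucleotide masses, bond-type spring constants, distance
    cutoff), and solves for intrinsic vibrational modes either directly or
    through a symmetry-constrained reduction that uses a single repeated
    subunit plus its inter-subunit couplings. Includes structure validation
    (hydrogen-bond lengths, sticky-end pairing, steric clashes), polyhedral
    tile-graph topology checks, classification of mode shapes into the
    ring/cage motion taxonomy (inner-circle translations and rotations,
    zigzag, spiderlike, breathing and torsional motions), and PDB/NMD/CSV
    export of structures and modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
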