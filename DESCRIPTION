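Package: latticefit
Title: High-Accuracy Lattice Models of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits protein atomic coordinates (C-alpha backbones and,
    optionally, side-chain centroids) onto discrete lattices, producing
    valid self-avoiding lattice protein models. Implements a chain-growth
    beam search that minimises distance RMSD with point-group symmetry
    filtering and Kabsch superposition including the mirror-image branch,
    and an alternative rotation-scanning coordinate-RMSD optimiser with
    rotational refinement. Supports the 2D-square, 3D-cubic,
    face-centred-cubic and knight's-walk lattices, fragmented PDB input,
    and PDB/XYZ/move-string output, together with synthetic fixture
    generation and exhaustive brute-force oracles for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
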