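Package: covflex
Title: Flexible-Receptor Covalent Docking and Binding-Site Repacking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pose prediction for covalent ligands binding to flexible
    pockets, modelled on the cysteine-targeted inhibitors of the KRAS
    switch-II site. Provides ensemble chi-angle profiling to classify
    binding-site residues as flexible or blocking, temporary alanine
    masking of blocking residues before docking, anchor-first covalent
    adduct enumeration with bond-geometry filtering, rotamer-library
    side-chain repacking with torsional refinement, greedy pose
    clustering, symmetry-corrected heavy-atom ligand RMSD, and a
    cross-docking benchmark harness with top-N success curves. Includes
    a deterministic synthetic mini-pocket generator with planted ground
    truth, a toy Monte Carlo loop-transition simulator motivating
    glycine loop mutations for free-energy receptor preparation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineR,
    graphics,
    grDevices,
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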