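Package: chiscan
Title: Structure-Specific Protein Side-Chain Rotamer Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates rotamer libraries that are specific to a target
    protein structure rather than averaged over the Protein Data Bank.
    Each side chain is scanned over its chi dihedral-angle grid against
    its actual backbone environment using homogeneous-coordinate
    transform chains and dead-end elimination, and conformations are
    scored with a weighted pairwise force field (Lennard-Jones, Coulomb,
    hydrogen bond, torsion) under a smooth distance cutoff. Includes
    PDBx/mmCIF input and output, symmetry-aware evaluation metrics
    (best-case RMSD and best-case dihedral angles), particle swarm
    optimisation for weight calibration, and an ideal-geometry fixture
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
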