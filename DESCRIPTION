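Package: pepbuildr
Title: Peptide Tertiary Structure Modelling with Modified Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds all-atom three-dimensional models of short peptides
    (7-25 residues) from sequence plus secondary-structure and beta-turn
    torsion restraints, using internal-coordinate (NeRF) chain extension
    and a backbone-dependent rotamer library.  Handles residue
    modifications common in therapeutic peptides: D-amino acids, N/C
    terminal caps, head-to-tail and disulfide cyclization, and
    non-natural or post-translationally modified side chains supplied as
    plain-text residue templates.  Models are refined with a lightweight
    molecular-mechanics engine (steepest-descent/conjugate-gradient
    minimization and short vacuum molecular dynamics) and evaluated
    against experimental multi-model ensembles with Kabsch superposition,
    RMSD/CA-RMSD/B-RMSD and rigid-core machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
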