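Package: EnsembleRange
Title: Objective Residue Ranges for Superimposing Protein Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines amino-acid residue ranges for the global superposition of
    multi-conformer protein structure bundles, such as NMR ensembles. Residues in
    locally well-ordered regions are identified through circular order parameters of
    all rotatable dihedral angles with an automatically chosen cutoff; their CA atoms
    are clustered on the inter-atomic distance-variance matrix to decompose the
    structure into rigid domains; and each domain's residue set is refined by
    gap-penalized iterative removal of residues until the decrease in the ensemble
    RMSD per removed residue becomes insignificant. Includes a seeded generator of
    synthetic structure bundles with known ordered/disordered ground truth, multi-model
    PDB input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), bio3d, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'params.R'
    'pdb-io.R'
    'torsions.R'
    'geometry.R'
    'order-parameters.R'
    'clustering.R'
    'refine.R'
    'pipeline.R'
    'report.R'
    'synthetic.R'
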