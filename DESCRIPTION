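Package: chuckles
Title: Peptide Assembly and Graph Featurization from CHUCKLES Monomer Notation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts peptide sequences containing noncanonical amino acids,
    D-residues, peptoid units, end caps, polymer units, and head-to-tail
    cycles into atom-mapped SMILES, molecule objects, and machine-learning
    ready representations. Residues are defined in a user-customizable
    library using the CHUCKLES convention (monomer SMILES written
    N-terminus, alpha carbon, C-terminus so that peptides assemble by
    string concatenation), with atom-map numbers on the terminal nitrogen
    and carbonyl carbon to track peptide bonds. Provides molecular graph
    featurization (atom and bond feature matrices, adjacency, per-atom
    residue mapping, L/D residue flags, CIP chirality columns), Morgan and
    MACCS fingerprints, one-hot sequence encodings, L-to-D and L-to-peptoid
    analog generation, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: OpenBabel (the obabel executable on the PATH)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
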