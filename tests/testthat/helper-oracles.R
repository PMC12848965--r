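# shared fixtures and independent oracles

# default library, loaded once without per-entry revalidation (one test
# exercises the full validation pass explicitly)
default_lib <- function() {
  if (is.null(.helper_env$lib))
    .helper_env$lib <- load_default_library(validate = FALSE)
  .helper_env$lib
}
.helper_env <- new.env()

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "K", "L", "M", "F", "P", "S", "T", "W", "Y", "V")

# independent sequence -> molecule converter: RDKit's one-letter builder,
# run through the python interpreter in one batched call
rdkit_seq_smiles <- function(seqs) {
  script <- 'import sys
from rdkit import Chem
for line in open(sys.argv[1]):
    s = line.strip()
    if s:
        print(Chem.MolToSmiles(Chem.MolFromSequence(s)))
'
  pyf <- tempfile(fileext = ".py"); writeLines(script, pyf)
  inf <- tempfile(); writeLines(seqs, inf)
  out <- system2("python", c(pyf, inf), stdout = TRUE, stderr = FALSE)
  stopifnot(length(out) == length(seqs))
  out
}

# independent CIP oracle: RDKit's modern CIP labeler; returns one
# ";"-joined sorted label multiset per input SMILES
rdkit_cip_labels <- function(smiles) {
  script <- 'import sys
from rdkit import Chem
from rdkit.Chem import rdCIPLabeler
for line in open(sys.argv[1]):
    s = line.strip()
    if not s:
        continue
    m = Chem.MolFromSmiles(s)
    rdCIPLabeler.AssignCIPLabels(m)
    labs = sorted(a.GetProp("_CIPCode") for a in m.GetAtoms()
                  if a.HasProp("_CIPCode"))
    print(";".join(labs))
'
  pyf <- tempfile(fileext = ".py"); writeLines(script, pyf)
  inf <- tempfile(); writeLines(smiles, inf)
  out <- system2("python", c(pyf, inf), stdout = TRUE, stderr = FALSE)
  stopifnot(length(out) == length(smiles))
  out
}

# random sequences over the whole residue library: interior tokens from
# non-cap classes, optional caps on linear peptides
random_library_sequence <- function(lib, cyclic = FALSE, max_len = 8L) {
  e <- lib$entries
  interior <- e$token[!e$class %in% c("n_cap", "c_cap")]
  k <- sample(if (cyclic) 2:max_len else 1:max_len, 1)
  tokens <- sample(interior, k, replace = TRUE)
  if (!cyclic && stats::runif(1) < 0.3)
    tokens <- c(sample(e$token[e$class == "n_cap"], 1), tokens)
  if (!cyclic && stats::runif(1) < 0.3)
    tokens <- c(tokens, sample(e$token[e$class == "c_cap"], 1))
  paste(tokens, collapse = "")
}
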