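# -- CHUCKLES assembler -------------------------------------------------------
#
# Peptide construction is string surgery on the monomer SMILES: every
# residue but the last loses the terminal hydroxyl "O" of its "(=O)O"
# tail, every residue but the first has the hydrogen count of its leading
# nitrogen bracket decremented by one, and the pieces are concatenated in
# order.  Head-to-tail cycles additionally close a ring between the first
# residue's nitrogen and the last residue's carbonyl carbon with a "%NN"
# ring label.  Atom maps 1/2 stay on the termini; residue membership is
# recovered structurally by cutting the map-2 C / map-1 N bonds.

# decrement the H count of the leading atom bracket ("[NH2:1]" -> "[NH:1]")
.decrement_bracket_h <- function(smiles, token = "?") {
  m <- regexec("^\\[([A-Za-z][a-z]?)(@@?)?(H([0-9]*))?((?:[+-][0-9]*)?)((?::[0-9]+)?)\\]",
               smiles)[[1]]
  if (m[1] == -1L)
    stop("residue '", token, "' does not start with an atom bracket")
  parts <- regmatches(smiles, list(m))[[1]]
  if (!nzchar(parts[4]))
    stop("residue '", token, "' cannot accept an N-terminal bond: ",
         "its leading atom has no hydrogen to remove")
  h <- if (!nzchar(parts[5])) 1L else as.integer(parts[5])
  h <- h - 1L
  hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  head <- paste0("[", parts[2], parts[3], hstr, parts[6], parts[7], "]")
  paste0(head, substr(smiles, attr(m, "match.length")[1] + 1L,
                      nchar(smiles)))
}

# drop the hydroxyl O of the required "(=O)O" tail
.drop_acid_hydroxyl <- function(smiles, token = "?") {
  if (!grepl("\\(=O\\)O$", smiles))
    stop("residue '", token, "' cannot donate a C-terminal bond: ",
         "its CHUCKLES string does not end in '(=O)O'")
  substr(smiles, 1L, nchar(smiles) - 1L)
}

# first unused two-digit ring label, scanning %99 downwards
.free_ring_label <- function(pieces) {
  joined <- paste(pieces, collapse = "")
  used <- integer()
  for (m in regmatches(joined, gregexpr("%[0-9]{2}", joined))[[1]]) {
    used <- c(used, as.integer(substr(m, 2, 3)))
  }
  for (lab in 99:10) if (!(lab %in% used)) return(lab)
  stop("no free ring-closure label in %10-%99")
}

#' Assemble a peptide from a token sequence
#'
#' Builds the atom-mapped peptide SMILES and molecule from a sequence by
#' CHUCKLES concatenation, resolving each token in `library`.  For
#' head-to-tail cycles the first nitrogen and last carbonyl carbon are
#' additionally joined through a fresh `%NN` ring-closure label.
#'
#' @param x A sequence string or a [tokenize_sequence()] result.
#' @param library A `residue_library`.
#' @param cyclic Head-to-tail cyclic topology (ignored when `x` is already
#'   tokenized).
#' @return An `assembled_peptide`: list with `smiles` (atom-mapped),
#'   `mol` (a `chk_mol`), `tokens`, `topology`, `residue_of_atom`
#'   (1-based residue index per atom, in sequence order; see
#'   [export_graph()] for the 0-based serialized form), and
#'   `peptide_bonds` (two-column matrix of carbonyl-C / amide-N atom
#'   indices, one row per peptide bond).
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' pep <- assemble_peptide("GG", lib)
#' pep$smiles
#' canonical_smiles(pep$smiles)
#' @export
assemble_peptide <- function(x, library, cyclic = FALSE) {
  seq <- if (inherits(x, "tokenized_sequence")) x
  else tokenize_sequence(x, library, cyclic = cyclic)
  if (seq$topology == "head_to_tail_cyclic") {
    .assemble(seq, library, cyclic = TRUE)
  } else {
    .assemble(seq, library, cyclic = FALSE)
  }
}

.assemble <- function(seq, library, cyclic) {
  tokens <- seq$tokens
  k <- length(tokens)
  entries <- lapply(tokens, function(t) library[[t]])
  pieces <- vapply(entries, function(e) e$smiles, character(1))

  last_donates <- cyclic        # in a cycle the last residue also loses its O
  first_accepts <- cyclic       # and the first nitrogen also loses an H
  for (i in seq_len(k)) {
    if (i < k || last_donates)
      pieces[i] <- .drop_acid_hydroxyl(pieces[i], tokens[i])
    if (i > 1L || first_accepts)
      pieces[i] <- .decrement_bracket_h(pieces[i], tokens[i])
  }

  if (cyclic) {
    lab <- .free_ring_label(pieces)
    labtok <- sprintf("%%%02d", lab)
    # after the first residue's leading (map-1) bracket ...
    m <- regexpr("^\\[[^]]+\\]", pieces[1])
    if (m == -1L) stop("first residue does not start with an atom bracket")
    pieces[1] <- paste0(substr(pieces[1], 1, attr(m, "match.length")),
                        labtok,
                        substr(pieces[1], attr(m, "match.length") + 1L,
                               nchar(pieces[1])))
    # ... and after the last residue's map-2 bracket, before its (=O) branch
    if (!grepl("\\(=O\\)$", pieces[k]))
      stop("last residue does not end with a donatable carbonyl")
    pieces[k] <- sub("\\(=O\\)$", paste0(labtok, "(=O)"), pieces[k])
  }

  smiles <- paste(pieces, collapse = "")
  mol <- tryCatch(parse_smiles(smiles), error = function(e) e)
  if (inherits(mol, "error")) {
    junction <- .diagnose_junction(pieces)
    stop("assembled SMILES failed to parse",
         if (!is.na(junction)) paste0(" (junction ", junction, ")") else "",
         ": ", conditionMessage(mol))
  }

  split <- .split_residues(mol, k)

  structure(
    list(smiles = smiles, mol = mol, tokens = tokens,
         topology = seq$topology,
         residue_of_atom = split$residue_of_atom,
         peptide_bonds = split$peptide_bonds),
    class = "assembled_peptide"
  )
}

# locate the first cumulative prefix that fails to parse
.diagnose_junction <- function(pieces) {
  for (i in seq_along(pieces)) {
    pref <- paste(pieces[seq_len(i)], collapse = "")
    ok <- !inherits(tryCatch(parse_smiles(pref), error = function(e) e),
                    "chk_mol")
    if (ok) return(i - 1L)
  }
  NA_integer_
}

# cut every map-2 carbon -- map-1 nitrogen bond; components are the residues
.split_residues <- function(mol, k) {
  at <- mol$atoms
  b <- mol$bonds
  is_pb <- logical(nrow(b))
  cn <- matrix(integer(), ncol = 2)
  for (kk in seq_len(nrow(b))) {
    i <- b$a1[kk]; j <- b$a2[kk]
    if (at$map[i] == 2L && at$element[i] == "C" &&
        at$map[j] == 1L && at$element[j] == "N") {
      is_pb[kk] <- TRUE; cn <- rbind(cn, c(i, j))
    } else if (at$map[j] == 2L && at$element[j] == "C" &&
               at$map[i] == 1L && at$element[i] == "N") {
      is_pb[kk] <- TRUE; cn <- rbind(cn, c(j, i))
    }
  }
  g <- igraph::graph_from_data_frame(
    d = b[!is_pb, c("a1", "a2"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(at))))
  comp <- igraph::components(g)$membership
  if (max(comp) != k)
    stop("residue splitting produced ", max(comp), " fragments for ", k,
         " residues; check the library's atom maps")
  # components in sequence order = order of first atom (concatenation order)
  first_atom <- vapply(seq_len(max(comp)), function(cc) min(which(comp == cc)),
                       integer(1))
  remap <- order(first_atom)
  residue_of_atom <- match(comp, remap)
  # order peptide bonds by the residue index of their carbonyl side
  if (nrow(cn)) {
    cn <- cn[order(residue_of_atom[cn[, 1]]), , drop = FALSE]
  }
  colnames(cn) <- c("carbonyl_c", "amide_n")
  list(residue_of_atom = residue_of_atom, peptide_bonds = cn)
}

#' @export
print.assembled_peptide <- function(x, ...) {
  cat("<assembled_peptide> ", paste(x$tokens, collapse = ""), " [",
      x$topology, "]\n  ", x$smiles, "\n  ", mol_natoms(x$mol),
      " atoms, ", nrow(x$peptide_bonds), " peptide bond(s)\n", sep = "")
  invisible(x)
}

#' Residue membership of every atom
#'
#' Returns the per-atom residue index vector, aligned with the molecule's
#' atom order; residue indices follow sequence order (caps count as
#' residues).
#'
#' @param peptide An `assembled_peptide`.
#' @return Integer vector of length `mol_natoms(peptide$mol)` with values
#'   in `1..k`.
#' @export
residue_mapping <- function(peptide) {
  stopifnot(inherits(peptide, "assembled_peptide"))
  peptide$residue_of_atom
}

#' Expected formula of an assembled peptide
#'
#' Sum of the residue formulas minus one water per peptide bond; used to
#' verify mass conservation of the assembly.
#'
#' @param tokens Character vector of tokens.
#' @param library A `residue_library`.
#' @param n_bonds Number of peptide bonds formed.
#' @return Named integer element-count vector.
#' @export
expected_formula <- function(tokens, library, n_bonds) {
  fs <- lapply(tokens, function(t) mol_formula(parse_smiles(library[[t]]$smiles)))
  args <- c(fs, list(.WATER))
  do.call(formula_sum, c(args, list(mult = c(rep(1, length(fs)), -n_bonds))))
}
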