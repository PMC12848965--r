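# -- molecule-level utilities -------------------------------------------------

#' Molecular formula of a molecule
#'
#' Counts every element, including implicit and bracket hydrogens.
#'
#' @param mol A `chk_mol` object.
#' @return Named integer vector of element counts (e.g. `c(C = 2, H = 5,
#'   N = 1, O = 2)` for glycine), in Hill order.
#' @seealso [formula_string()], [formula_sum()]
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  v <- stats::setNames(as.integer(counts), names(counts))
  nh <- sum(mol$atoms$hcount)
  if (nh > 0) v["H"] <- (if ("H" %in% names(v)) v[["H"]] else 0L) + nh
  .hill_order(v)
}

.hill_order <- function(v) {
  v <- v[v != 0L]
  els <- names(v)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  v[ord]
}

#' Format an element-count vector as a formula string
#'
#' @param counts Named integer vector as returned by [mol_formula()].
#' @return A Hill-order formula string such as `"C2H5NO2"`.
#' @export
formula_string <- function(counts) {
  counts <- .hill_order(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Add element-count vectors
#'
#' Sums (or, with negative `mult`, subtracts) molecular formulas given as
#' named count vectors; used to check that an assembled peptide's formula
#' equals the sum of its residue formulas minus one water per peptide bond.
#'
#' @param ... Named integer vectors of element counts.
#' @param mult Optional numeric multipliers, one per vector.
#' @return Named integer vector of summed counts in Hill order.
#' @examples
#' gly <- c(C = 2, H = 5, N = 1, O = 2)
#' water <- c(H = 2, O = 1)
#' formula_sum(gly, gly, water, mult = c(1, 1, -1)) # glycylglycine
#' @export
formula_sum <- function(..., mult = NULL) {
  vs <- list(...)
  if (is.null(mult)) mult <- rep(1, length(vs))
  stopifnot(length(mult) == length(vs))
  acc <- integer()
  for (k in seq_along(vs)) {
    v <- vs[[k]]
    for (el in names(v)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0L) +
        as.integer(mult[k] * v[[el]])
    }
  }
  if (any(acc < 0L)) stop("negative element count in formula arithmetic")
  .hill_order(acc)
}

.WATER <- c(H = 2L, O = 1L)

#' Canonical SMILES via OpenBabel
#'
#' Canonicalizes SMILES strings with the OpenBabel command-line converter
#' (one batched call per vector).  Atom maps are dropped in the canonical
#' form, so two atom-mapped assemblies of the same molecule compare equal.
#' Used throughout as the structural equality oracle.
#'
#' @param smiles SMILES string(s).
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  .obabel_convert(smiles, "-ocan", label = "canonicalize")
}

#' Standard InChI of a molecule
#'
#' Computes the standard InChI (including the stereo layer) through the
#' OpenBabel command-line converter.  InChI generation stays fast on large
#' peptides, so this is the preferred structural-identity check for long
#' sequences.
#'
#' @param smiles SMILES string(s).
#' @return Character vector of standard InChI strings.
#' @export
mol_inchi <- function(smiles) {
  .obabel_convert(smiles, "-oinchi", label = "compute InChI for")
}

.obabel_convert <- function(smiles, outflag, label) {
  stopifnot(is.character(smiles), length(smiles) >= 1L, !anyNA(smiles))
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) stop("the 'obabel' executable is not on the PATH")
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(smiles, inf)
  out <- suppressWarnings(system2(obabel, c("-ismi", inf, outflag),
                                  stdout = TRUE, stderr = FALSE))
  out <- sub("[\t ].*$", "", out)
  out <- out[nzchar(out)]
  if (length(out) != length(smiles)) {
    # locate the first failing molecule for the error message
    for (s in smiles) {
      one_in <- tempfile(fileext = ".smi"); writeLines(s, one_in)
      one <- suppressWarnings(system2(obabel, c("-ismi", one_in, outflag),
                                      stdout = TRUE, stderr = FALSE))
      unlink(one_in)
      one <- sub("[\t ].*$", "", one)
      if (!length(one) || !nzchar(one[1]))
        stop("OpenBabel failed to ", label, " '", s, "'")
    }
    stop("OpenBabel ", label, " returned ", length(out), " results for ",
         length(smiles), " molecules")
  }
  out
}

#' Invert every tetrahedral stereocenter in a SMILES string
#'
#' Produces the mirror-image (enantiomeric) SMILES by swapping `@` and `@@`
#' inside every atom bracket.  Purely textual: the atom order is unchanged.
#'
#' @param smiles A SMILES string.
#' @return The SMILES of the enantiomer.
#' @examples
#' invert_stereo("N[C@@H](C)C(=O)O") # L-alanine -> D-alanine
#' @export
invert_stereo <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  # swap via a placeholder so @@ -> @ and @ -> @@ don't collide
  s <- gsub("@@", "\001", smiles, fixed = TRUE)
  s <- gsub("@", "@@", s, fixed = TRUE)
  gsub("\001", "@", s, fixed = TRUE)
}

# ring perception: bonds in cycles are the non-bridge edges
.ring_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(logical(0))
  g <- .mol_igraph(mol)
  br <- igraph::bridges(g)
  inring <- rep(TRUE, nrow(mol$bonds))
  inring[as.integer(br)] <- FALSE
  inring
}

.ring_atoms <- function(mol, ring_bonds = .ring_bonds(mol)) {
  inring <- rep(FALSE, nrow(mol$atoms))
  if (any(ring_bonds)) {
    inring[unique(c(mol$bonds$a1[ring_bonds], mol$bonds$a2[ring_bonds]))] <- TRUE
  }
  inring
}

# smallest ring containing bond k, or 0 when acyclic
.smallest_ring_size <- function(mol, k, g = .mol_igraph(mol)) {
  gk <- igraph::delete_edges(g, k)
  d <- igraph::distances(gk, v = mol$bonds$a1[k], to = mol$bonds$a2[k])[1, 1]
  if (is.infinite(d)) 0L else as.integer(d + 1L)
}
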