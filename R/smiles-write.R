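# -- SMILES writer ------------------------------------------------------------
#
# Depth-first writer used for round-trip validation of library entries.
# Tetrahedral tags are re-derived for the emitted neighbor order by
# permutation parity against the parsed order, so stereochemistry survives
# parse -> write -> parse.

#' Write a molecule back to SMILES
#'
#' Serializes a `chk_mol` by depth-first traversal from the first atom.
#' The output is not canonical (use [canonical_smiles()] for canonical
#' forms) but is a valid SMILES of the same molecule, preserving atom maps,
#' charges, hydrogen counts and tetrahedral stereochemistry.
#'
#' @param mol A `chk_mol` object.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol) {
  nat <- nrow(mol$atoms)
  at <- mol$atoms
  bonds <- mol$bonds

  bond_ix <- vector("list", nat)  # incident bond indices per atom
  for (k in seq_len(nrow(bonds))) {
    bond_ix[[bonds$a1[k]]] <- c(bond_ix[[bonds$a1[k]]], k)
    bond_ix[[bonds$a2[k]]] <- c(bond_ix[[bonds$a2[k]]], k)
  }
  other_end <- function(k, i) if (bonds$a1[k] == i) bonds$a2[k] else bonds$a1[k]

  # -- spanning DFS: children + back edges -----------------------------------
  parent <- rep(0L, nat)
  visited <- rep(FALSE, nat)
  children <- vector("list", nat)
  closures <- vector("list", nat)  # list of c(label, partner, bond) per atom
  n_label <- 0L
  seen_bond <- rep(FALSE, nrow(bonds))

  # neighbor order as parsed, for traversal stability
  nbr_order <- lapply(seq_len(nat), function(i) {
    v <- mol$stereo_nbrs[[i]]
    v[v > 0L]
  })

  dfs_rec <- function(i) {
    for (j in nbr_order[[i]]) {
      k <- bond_ix[[i]][vapply(bond_ix[[i]],
                               function(b) other_end(b, i) == j, logical(1))][1]
      if (seen_bond[k]) next
      if (!visited[j]) {
        seen_bond[k] <<- TRUE
        visited[j] <<- TRUE
        parent[j] <<- i
        children[[i]] <<- c(children[[i]], j)
        dfs_rec(j)
      } else {
        seen_bond[k] <<- TRUE
        n_label <<- n_label + 1L
        closures[[i]] <<- c(closures[[i]], list(c(n_label, j, k)))
        closures[[j]] <<- c(closures[[j]], list(c(n_label, i, k)))
      }
    }
  }

  visited[1L] <- TRUE
  dfs_rec(1L)
  if (!all(visited)) stop("disconnected molecule cannot be written")

  bond_sym <- function(k) {
    o <- bonds$order[k]
    if (o == 2) "=" else if (o == 3) "#"
    else if (o == 1.5) ""
    else if (at$aromatic[bonds$a1[k]] && at$aromatic[bonds$a2[k]]) "-"
    else ""
  }

  label_tok <- function(lab) if (lab < 10L) as.character(lab) else sprintf("%%%02d", lab)

  atom_token <- function(i, emitted) {
    el <- at$element[i]
    arom <- at$aromatic[i]
    sym <- if (arom) tolower(el) else el
    chi <- at$chiral[i]
    if (nzchar(chi)) chi <- .rederive_tag(mol, i, emitted)
    needs_bracket <- at$charge[i] != 0L || at$map[i] != 0L || nzchar(chi) ||
      !(el %in% .ORGANIC_SUBSET) ||
      (arom && !(tolower(el) %in% .AROMATIC_SUBSET)) ||
      at$hcount[i] != .default_h(mol, i)
    if (!needs_bracket) return(sym)
    h <- at$hcount[i]
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    chg <- at$charge[i]
    cstr <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
    else sprintf("%+d", chg)
    mstr <- if (at$map[i] != 0L) paste0(":", at$map[i]) else ""
    paste0("[", sym, chi, hstr, cstr, mstr, "]")
  }

  # implicit H the reader would assign to atom i written without a bracket
  .default_h <- function(mol, i) {
    el <- at$element[i]
    if (!(el %in% .ORGANIC_SUBSET)) return(-1L)
    deg <- length(bond_ix[[i]])
    osum <- sum(bonds$order[bond_ix[[i]]])
    if (at$aromatic[i]) {
      if (el == "C") return(max(0L, 3L - deg)) else return(0L)
    }
    val <- .BASE_VALENCE[[el]] + at$charge[i]
    cand <- c(val, .ALT_VALENCE[[el]] + at$charge[i])
    cand <- cand[cand >= osum]
    if (length(cand) == 0L) return(-1L)
    as.integer(cand[1] - osum)
  }

  emit <- function(i) {
    # emitted neighbor order: parent, implicit H slots, closures, children
    emitted <- integer()
    if (parent[i] > 0L) emitted <- parent[i]
    if (at$hcount[i] > 0L) emitted <- c(emitted, rep(0L, at$hcount[i]))
    for (cl in closures[[i]]) emitted <- c(emitted, cl[2])
    emitted <- c(emitted, children[[i]])

    out <- atom_token(i, emitted)
    for (cl in closures[[i]]) {
      out <- paste0(out, bond_sym(cl[3]), label_tok(cl[1]))
    }
    ch <- children[[i]]
    if (length(ch)) {
      for (m in seq_along(ch)) {
        j <- ch[m]
        k <- bond_ix[[i]][vapply(bond_ix[[i]],
                                 function(b) other_end(b, i) == j, logical(1))][1]
        piece <- paste0(bond_sym(k), emit(j))
        if (m < length(ch)) piece <- paste0("(", piece, ")")
        out <- paste0(out, piece)
      }
    }
    out
  }

  emit(1L)
}

# re-derive @/@@ for a new neighbor order by permutation parity
.rederive_tag <- function(mol, i, emitted) {
  stored <- mol$stereo_nbrs[[i]]
  tag <- mol$atoms$chiral[i]
  if (length(stored) != 4L || sum(stored == 0L) > 1L) return("")
  if (length(emitted) != 4L) return("")
  if (!identical(sort(stored), sort(emitted))) return("")
  perm <- match(emitted, stored)
  if (anyNA(perm)) return("")
  if (.perm_sign(perm) > 0) tag else if (tag == "@") "@@" else "@"
}

.perm_sign <- function(p) {
  n <- length(p)
  sign <- 1L
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    j <- i; clen <- 0L
    while (!seen[j]) { seen[j] <- TRUE; j <- p[j]; clen <- clen + 1L }
    if (clen %% 2L == 0L) sign <- -sign
  }
  sign
}
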