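# -- CIP R/S assignment -------------------------------------------------------
#
# Hierarchical sphere-by-sphere ranking by atomic number with duplicate
# (phantom) atoms for multiple bonds and ring closures.  This covers the
# priority decisions that arise in peptide chemistry (alpha carbons and
# side-chain stereocenters of the packaged residue space); higher CIP rules
# (isotopes, like/unlike descriptor comparisons) are out of scope.  Aromatic
# atoms receive a single phantom carrying the heaviest aromatic-neighbor
# atomic number, standing in for the Kekule duplicate.

.ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Zn = 30, Se = 34,
  Br = 35, I = 53
)

.atomic_number <- function(el) {
  z <- .ATOMIC_NUMBER[el]
  if (anyNA(z)) stop("no atomic number registered for element(s): ",
                     paste(unique(el[is.na(z)]), collapse = ", "))
  unname(z)
}

# children of `node` (approaching from `parent_node`) in the CIP digraph.
# Real children are expanded further; phantoms (negative encoding -Z) are
# terminal.  `path` holds the atoms already on the root-to-node path; a ring
# closure back onto the path yields a phantom of the revisited atom.
.cip_children <- function(mol, node, parent_node, path, zcache) {
  at <- mol$atoms
  kids_real <- integer()
  kids_phantom <- numeric()
  b <- mol$bonds
  inc <- which(b$a1 == node | b$a2 == node)
  arom_z <- integer()
  for (k in inc) {
    j <- if (b$a1[k] == node) b$a2[k] else b$a1[k]
    ord <- b$order[k]
    if (b$aromatic[k]) arom_z <- c(arom_z, zcache[j])
    # duplicated atoms for the multiple-bond portion, on this side
    if (ord == 2) kids_phantom <- c(kids_phantom, zcache[j])
    if (ord == 3) kids_phantom <- c(kids_phantom, zcache[j], zcache[j])
    if (j == parent_node) next
    if (j %in% path) {
      kids_phantom <- c(kids_phantom, zcache[j])  # ring-closure duplicate
    } else {
      kids_real <- c(kids_real, j)
    }
  }
  if (length(arom_z)) kids_phantom <- c(kids_phantom, max(arom_z))
  # implicit hydrogens are terminal Z=1 children
  nh <- at$hcount[node]
  if (nh > 0L) kids_phantom <- c(kids_phantom, rep(1, nh))
  list(real = kids_real, phantom = kids_phantom)
}

# sphere-by-sphere atomic-number profile of the branch entered from `center`
# through `first`.  Returns a list of numeric vectors (sorted descending),
# one per sphere, to a fixed depth.
.branch_profile <- function(mol, center, first, zcache, max_depth = 12L) {
  if (first == 0L) {
    return(list(1))  # implicit-H branch: a single hydrogen sphere
  }
  profiles <- list(zcache[first])
  # frontier: list of (node, parent, path)
  frontier <- list(list(node = first, parent = center, path = c(center, first)))
  depth <- 1L
  while (length(frontier) && depth < max_depth) {
    sphere <- numeric()
    nxt <- list()
    for (f in frontier) {
      ch <- .cip_children(mol, f$node, f$parent, f$path, zcache)
      sphere <- c(sphere, zcache[ch$real], ch$phantom)
      for (j in ch$real) {
        nxt[[length(nxt) + 1L]] <- list(node = j, parent = f$node,
                                        path = c(f$path, j))
      }
    }
    if (length(sphere) == 0L) break
    profiles[[length(profiles) + 1L]] <- sort(sphere, decreasing = TRUE)
    frontier <- nxt
    depth <- depth + 1L
  }
  profiles
}

# compare branch profiles: +1 if a > b, -1 if a < b, 0 tie
.compare_profiles <- function(a, b) {
  nmax <- max(length(a), length(b))
  for (d in seq_len(nmax)) {
    va <- if (d <= length(a)) a[[d]] else numeric()
    vb <- if (d <= length(b)) b[[d]] else numeric()
    lmax <- max(length(va), length(vb))
    if (lmax == 0L) next
    # shorter sphere padded with 0 (absent < any atom)
    va <- c(va, rep(0, lmax - length(va)))
    vb <- c(vb, rep(0, lmax - length(vb)))
    for (t in seq_len(lmax)) {
      if (va[t] > vb[t]) return(1L)
      if (va[t] < vb[t]) return(-1L)
    }
  }
  0L
}

#' CIP R/S codes for the stereocenters of a molecule
#'
#' Assigns an R or S descriptor to every atom carrying a tetrahedral
#' `@`/`@@` tag whose four substituents can be strictly ranked by
#' sphere-by-sphere atomic-number comparison (with duplicate atoms for
#' multiple bonds and rings).  Atoms without a tag, or whose substituents
#' tie under this ranking, are reported as `NA` ("not defined").
#'
#' @param mol A `chk_mol` object.
#' @return Character vector of length `mol_natoms(mol)` with values
#'   `"R"`, `"S"` or `NA`.
#' @examples
#' assign_cip(parse_smiles("N[C@@H](C)C(=O)O")) # L-alanine: S at the Ca
#' @export
assign_cip <- function(mol) {
  nat <- nrow(mol$atoms)
  out <- rep(NA_character_, nat)
  zcache <- .atomic_number(mol$atoms$element)
  for (i in seq_len(nat)) {
    tag <- mol$atoms$chiral[i]
    if (!nzchar(tag)) next
    nb <- mol$stereo_nbrs[[i]]
    if (length(nb) != 4L || sum(nb == 0L) > 1L) next
    profiles <- lapply(nb, function(j) .branch_profile(mol, i, j, zcache))
    # pairwise ranking; ties leave the descriptor undefined
    rank_ord <- seq_len(4L)
    cmp <- matrix(0L, 4, 4)
    tied <- FALSE
    for (a in 1:3) for (b in (a + 1):4) {
      c_ab <- .compare_profiles(profiles[[a]], profiles[[b]])
      if (c_ab == 0L) tied <- TRUE
      cmp[a, b] <- c_ab; cmp[b, a] <- -c_ab
    }
    if (tied) next
    prio <- order(rowSums(cmp), decreasing = TRUE)  # highest priority first
    # parity of the permutation taking the as-written neighbor order to
    # priority order; @@ is clockwise viewed from the first-listed neighbor
    perm <- match(nb[prio], nb)
    even <- .perm_sign(perm) > 0
    out[i] <- if (even) {
      if (tag == "@@") "R" else "S"
    } else {
      if (tag == "@@") "S" else "R"
    }
  }
  out
}
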