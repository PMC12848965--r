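# -- graph featurizer ---------------------------------------------------------
#
# Fixed feature layouts totalling 24 atom columns and 16 bond columns:
#
# atoms: element one-hot {C,N,O,S,F,Cl,Br,P,Se,other} (10) +
#        heavy-atom degree one-hot {1,2,3,4,other} (5) +
#        total-H one-hot {0,1,2,3} (4) + formal charge (1) +
#        aromatic flag (1) + ring flag (1) +
#        hybridization one-hot {sp2,sp3} (2; sp and other map to zeros)
#
# bonds: type one-hot {single,double,triple,aromatic} (4) +
#        conjugated (1) + ring (1) +
#        stereo one-hot {none, Z, E, other} (4) +
#        peptide-bond flag (1) + intra-residue flag (1) +
#        rotatable flag (1) + smallest-ring-size one-hot {5,6,other} (3)
#
# Optional chirality adds three one-hot columns {S, R, not defined} from
# CIP codes computed on the assembled molecule.

.ELEMENT_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "P", "Se")

.ATOM_FEATURE_NAMES <- c(
  paste0("element_", c(.ELEMENT_VOCAB, "other")),
  paste0("degree_", c(1:4, "other")),
  paste0("num_h_", 0:3),
  "formal_charge", "is_aromatic", "in_ring", "hyb_sp2", "hyb_sp3"
)

.BOND_FEATURE_NAMES <- c(
  paste0("bond_", c("single", "double", "triple", "aromatic")),
  "is_conjugated", "in_ring",
  paste0("stereo_", c("none", "z", "e", "other")),
  "is_peptide_bond", "is_intra_residue", "is_rotatable",
  paste0("ring_size_", c("5", "6", "other"))
)

.CHIRALITY_FEATURE_NAMES <- c("cip_s", "cip_r", "cip_not_defined")

#' Feature column names
#'
#' Column names of the node and bond feature matrices produced by
#' [build_graph()], in layout order.
#'
#' @param include_chirality Append the three chirality column names.
#' @return Character vector of length 24 (27 with chirality) or 16.
#' @export
atom_feature_names <- function(include_chirality = FALSE) {
  if (include_chirality) c(.ATOM_FEATURE_NAMES, .CHIRALITY_FEATURE_NAMES)
  else .ATOM_FEATURE_NAMES
}

#' @rdname atom_feature_names
#' @export
bond_feature_names <- function() .BOND_FEATURE_NAMES

# per-atom hybridization from bond orders: "sp3" all single, "sp2" aromatic
# or one double, "sp" triple or two doubles, terminal/other "sp3"
.hybridization <- function(mol) {
  nat <- nrow(mol$atoms)
  ndouble <- integer(nat); ntriple <- integer(nat); narom <- integer(nat)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    for (i in c(b$a1[k], b$a2[k])) {
      if (b$aromatic[k]) narom[i] <- narom[i] + 1L
      else if (b$order[k] == 2) ndouble[i] <- ndouble[i] + 1L
      else if (b$order[k] == 3) ntriple[i] <- ntriple[i] + 1L
    }
  }
  ifelse(ntriple > 0L | ndouble >= 2L, "sp",
         ifelse(narom > 0L | ndouble == 1L, "sp2", "sp3"))
}

# atoms capable of pi participation (multiple/aromatic bond) and heteroatoms
# with a lone pair: used for conjugation
.conjugation <- function(mol) {
  nat <- nrow(mol$atoms)
  b <- mol$bonds
  pi_atom <- logical(nat)
  for (k in seq_len(nrow(b))) {
    if (b$aromatic[k] || b$order[k] >= 2) {
      pi_atom[b$a1[k]] <- TRUE; pi_atom[b$a2[k]] <- TRUE
    }
  }
  lp_atom <- mol$atoms$element %in% c("N", "O", "S", "Se")
  conj <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    u <- b$a1[k]; v <- b$a2[k]
    if (b$aromatic[k]) { conj[k] <- TRUE; next }
    if (b$order[k] >= 2) {
      # a multiple bond is conjugated when an adjacent atom extends the
      # pi system or carries a lone pair
      adj <- setdiff(unique(c(
        b$a1[b$a2 %in% c(u, v)], b$a2[b$a1 %in% c(u, v)])), c(u, v))
      conj[k] <- any(pi_atom[adj] | lp_atom[adj])
    } else {
      both_cap <- (pi_atom[u] || lp_atom[u]) && (pi_atom[v] || lp_atom[v])
      conj[k] <- both_cap && (pi_atom[u] || pi_atom[v])
    }
  }
  conj
}

.one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(as.character(value), levels)
  if (!is.na(i)) v[i] <- 1
  v
}

#' Feature vector of a single atom
#'
#' @param mol A `chk_mol`.
#' @param i Atom index.
#' @param extra_elements Extra element symbols routed to the `other`
#'   element column instead of raising an error.
#' @return Numeric vector of length 24, named per
#'   [atom_feature_names()].
#' @export
atom_feature_vector <- function(mol, i, extra_elements = character()) {
  .atom_features(mol, extra_elements)[i, ]
}

.atom_features <- function(mol, extra_elements = character()) {
  at <- mol$atoms
  unknown <- setdiff(unique(at$element), c(.ELEMENT_VOCAB, extra_elements))
  if (length(unknown))
    stop("element(s) ", paste(unknown, collapse = ", "),
         " outside the feature vocabulary; supply a custom residue library ",
         "and list them in 'extra_elements' to featurize them as 'other'")
  deg <- .degrees(mol)
  hyb <- .hybridization(mol)
  ring_atom <- .ring_atoms(mol)
  n <- nrow(at)
  M <- matrix(0, n, length(.ATOM_FEATURE_NAMES),
              dimnames = list(NULL, .ATOM_FEATURE_NAMES))
  for (i in seq_len(n)) {
    el <- if (at$element[i] %in% .ELEMENT_VOCAB) at$element[i] else "other"
    M[i, ] <- c(
      .one_hot(el, c(.ELEMENT_VOCAB, "other")),
      .one_hot(if (deg[i] %in% 1:4) deg[i] else "other", c(1:4, "other")),
      .one_hot(at$hcount[i], 0:3),
      at$charge[i],
      as.numeric(at$aromatic[i]),
      as.numeric(ring_atom[i]),
      .one_hot(hyb[i], c("sp2", "sp3"))
    )
  }
  M
}

#' Feature vector of a single bond
#'
#' @param peptide An `assembled_peptide`.
#' @param k Bond index.
#' @return Numeric vector of length 16, named per
#'   [bond_feature_names()].
#' @export
bond_feature_vector <- function(peptide, k) {
  .bond_features(peptide)[k, ]
}

.bond_features <- function(peptide) {
  mol <- peptide$mol
  b <- mol$bonds
  nb <- nrow(b)
  res <- peptide$residue_of_atom
  pb <- peptide$peptide_bonds

  is_pb <- logical(nb)
  if (nrow(pb)) {
    for (r in seq_len(nrow(pb))) {
      hit <- which((b$a1 == pb[r, 1] & b$a2 == pb[r, 2]) |
                   (b$a1 == pb[r, 2] & b$a2 == pb[r, 1]))
      is_pb[hit] <- TRUE
    }
  }

  ring <- .ring_bonds(mol)
  conj <- .conjugation(mol)
  deg <- .degrees(mol)
  g <- .mol_igraph(mol)

  # amide C-N single bonds (carbonyl carbon to nitrogen) are not rotatable
  carbonyl <- vapply(seq_len(nrow(mol$atoms)), function(i)
    mol$atoms$element[i] == "C" && .is_carbonyl(mol, i), logical(1))

  M <- matrix(0, nb, length(.BOND_FEATURE_NAMES),
              dimnames = list(NULL, .BOND_FEATURE_NAMES))
  for (k in seq_len(nb)) {
    type <- if (b$aromatic[k]) "aromatic"
    else c("single", "double", "triple")[b$order[k]]
    u <- b$a1[k]; v <- b$a2[k]
    amide <- b$order[k] == 1 && !b$aromatic[k] &&
      ((carbonyl[u] && mol$atoms$element[v] == "N") ||
       (carbonyl[v] && mol$atoms$element[u] == "N"))
    rot <- type == "single" && !ring[k] && deg[u] >= 2 && deg[v] >= 2 && !amide
    rs <- if (ring[k]) .smallest_ring_size(mol, k, g) else 0L
    M[k, ] <- c(
      .one_hot(type, c("single", "double", "triple", "aromatic")),
      as.numeric(conj[k]),
      as.numeric(ring[k]),
      .one_hot("none", c("none", "z", "e", "other")),
      as.numeric(is_pb[k]),
      as.numeric(res[u] == res[v]),
      as.numeric(rot),
      if (ring[k]) .one_hot(if (rs %in% c(5L, 6L)) rs else "other",
                            c("5", "6", "other"))
      else numeric(3)
    )
  }
  M
}

#' Build the graph representation of an assembled peptide
#'
#' Produces the node feature matrix (n_atoms x 24, or x 27 with
#' chirality), bond feature matrix (n_bonds x 16), 2 x E adjacency,
#' per-atom residue mapping and per-residue L/D flags.
#'
#' @param peptide An `assembled_peptide`.
#' @param library The `residue_library` the peptide was assembled from
#'   (source of the per-residue L/D flags).
#' @param include_chirality Add the three CIP chirality columns
#'   (S / R / not defined) to the node features.
#' @param directed_duplication List every bond in both directions
#'   (E = 2 x n_bonds), the form message-passing frameworks expect;
#'   `FALSE` lists each bond once.
#' @param extra_elements Extra element symbols allowed through to the
#'   `other` element column.
#' @return A `peptide_graph`: list with `node_features`, `edge_features`,
#'   `adjacency` (2 x E integer matrix of 1-based atom indices),
#'   `residue_of_atom`, `residue_flags` (k x 2), `tokens`, `smiles`,
#'   `include_chirality`, `directed_duplication`.
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' g <- build_graph(assemble_peptide("AG", lib), lib)
#' dim(g$node_features)
#' @export
build_graph <- function(peptide, library, include_chirality = FALSE,
                        directed_duplication = TRUE,
                        extra_elements = character()) {
  stopifnot(inherits(peptide, "assembled_peptide"))
  mol <- peptide$mol

  node <- .atom_features(mol, extra_elements)
  if (include_chirality) {
    cip <- assign_cip(mol)
    chir <- t(vapply(cip, function(code) {
      if (is.na(code)) c(0, 0, 1)
      else if (code == "S") c(1, 0, 0)
      else c(0, 1, 0)
    }, numeric(3)))
    dimnames(chir) <- list(NULL, .CHIRALITY_FEATURE_NAMES)
    node <- cbind(node, chir)
  }

  edge <- .bond_features(peptide)
  adj <- t(as.matrix(mol$bonds[, c("a1", "a2")]))
  if (directed_duplication && ncol(adj) > 0) {
    adj <- cbind(adj, adj[2:1, , drop = FALSE])
    edge <- rbind(edge, edge)
  }
  dimnames(adj) <- NULL
  storage.mode(adj) <- "integer"

  flags <- t(vapply(peptide$tokens,
                    function(t) residue_flag(library[[t]]), integer(2)))
  dimnames(flags) <- NULL

  structure(
    list(node_features = node, edge_features = edge, adjacency = adj,
         residue_of_atom = peptide$residue_of_atom, residue_flags = flags,
         tokens = peptide$tokens, smiles = peptide$smiles,
         include_chirality = include_chirality,
         directed_duplication = directed_duplication),
    class = "peptide_graph"
  )
}

#' @export
print.peptide_graph <- function(x, ...) {
  cat("<peptide_graph> ", nrow(x$node_features), " atoms x ",
      ncol(x$node_features), " features, ", ncol(x$adjacency),
      " directed edges x ", ncol(x$edge_features), " features, ",
      nrow(x$residue_flags), " residues\n", sep = "")
  invisible(x)
}

#' Export a peptide graph to a self-describing JSON container
#'
#' Writes all arrays with shapes and feature-name metadata so the file is
#' loadable without this package (residue and atom indices are serialized
#' 0-based for graph-learning consumers).  [import_graph()] restores the
#' object losslessly.
#'
#' @param graph A `peptide_graph`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "peptide_graph"))
  payload <- list(
    metadata = list(
      format = "chuckles-peptide-graph/1",
      atom_feature_names = colnames(graph$node_features),
      bond_feature_names = colnames(graph$edge_features),
      n_atoms = nrow(graph$node_features),
      n_bonds = ncol(graph$adjacency),
      n_residues = nrow(graph$residue_flags),
      include_chirality = graph$include_chirality,
      directed_duplication = graph$directed_duplication,
      index_base = 0L,
      tokens = graph$tokens,
      smiles = graph$smiles
    ),
    node_features = unname(graph$node_features),
    edge_features = unname(graph$edge_features),
    adjacency = graph$adjacency - 1L,
    residue_of_atom = graph$residue_of_atom - 1L,
    residue_flags = graph$residue_flags
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Import a peptide graph written by [export_graph()]
#'
#' @param path Path to the JSON container.
#' @return A `peptide_graph` identical to the exported one.
#' @export
import_graph <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  node <- p$node_features
  storage.mode(node) <- "double"
  colnames(node) <- p$metadata$atom_feature_names
  edge <- p$edge_features
  if (is.null(dim(edge))) edge <- matrix(edge, nrow = 0,
                                         ncol = length(p$metadata$bond_feature_names))
  storage.mode(edge) <- "double"
  colnames(edge) <- p$metadata$bond_feature_names
  adj <- p$adjacency
  storage.mode(adj) <- "integer"
  flags <- p$residue_flags
  storage.mode(flags) <- "integer"
  structure(
    list(node_features = node, edge_features = edge,
         adjacency = adj + 1L,
         residue_of_atom = as.integer(p$residue_of_atom) + 1L,
         residue_flags = flags,
         tokens = p$metadata$tokens, smiles = p$metadata$smiles,
         include_chirality = p$metadata$include_chirality,
         directed_duplication = p$metadata$directed_duplication),
    class = "peptide_graph"
  )
}
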