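# -- SMILES reader ------------------------------------------------------------
#
# The CHUCKLES workflow is string surgery on monomer SMILES, and downstream
# featurization needs per-atom access to atom maps, hydrogen counts and
# tetrahedral parity.  This reader covers the SMILES dialect the residue
# library is written in: organic-subset and bracket atoms, aromatic lowercase
# atoms, charges, atom maps, tetrahedral @/@@ tags, branches, and ring
# closures (1-9 and %NN).  Dot-disconnected structures and directional
# E/Z bond symbols (/ \) are rejected; the residue-library contract keeps
# both out of assembled peptides.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

.BASE_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1,
  P = 3, S = 2, Cl = 1, Br = 1, I = 1
)

# alternate valence states tried (in order) when the default is exceeded
.ALT_VALENCE <- list(N = 5L, P = 5L, S = c(4L, 6L))

.MAX_VALENCE <- c(
  B = 3, C = 4, N = 4, O = 3, F = 1,
  P = 6, S = 6, Cl = 1, Br = 1, I = 3, Se = 6
)

#' Parse a SMILES string into a molecule object
#'
#' Reads a SMILES string into an atom/bond table representation with the
#' bookkeeping needed for CHUCKLES assembly and featurization: atom-map
#' numbers, bracket hydrogen counts, implicit hydrogen assignment for
#' organic-subset atoms, and the neighbor order of each tetrahedral
#' stereocenter (required to interpret `@`/`@@`).
#'
#' @param smiles A single SMILES string.
#' @return An object of class `chk_mol`: a list with elements
#'   `atoms` (data frame: `element`, `aromatic`, `charge`, `hcount`,
#'   `map`, `chiral`), `bonds` (data frame: `a1`, `a2`, `order`,
#'   `aromatic`; `order` is 1.5 for aromatic bonds), `stereo_nbrs`
#'   (per-atom neighbor order, `0` marking an in-bracket implicit
#'   hydrogen), and `smiles` (the input string).
#' @examples
#' mol <- parse_smiles("[NH2:1][C@@H](C)[C:2](=O)O")
#' mol$atoms$element
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) stop("empty SMILES string")

  n <- 0L
  element <- character()
  aromatic <- logical()
  charge <- integer()
  hq <- integer()      # bracket H count; NA for organic-subset atoms
  map <- integer()
  chiral <- character()
  nbrs <- list()

  b_a1 <- integer(); b_a2 <- integer(); b_order <- numeric(); b_arom <- logical()

  prev <- 0L                 # atom awaiting the next bond
  stack <- integer()         # branch stack
  pending <- NA_character_   # bond symbol awaiting the next atom/closure
  open_rings <- list()       # label -> list(atom, pos, sym)

  s <- smiles
  pos <- 1L
  len <- nchar(s)

  add_atom <- function(el, arom, chg, h, mp, chi) {
    n <<- n + 1L
    element[n] <<- el; aromatic[n] <<- arom; charge[n] <<- chg
    hq[n] <<- h; map[n] <<- mp; chiral[n] <<- chi
    nbrs[[n]] <<- integer()
    n
  }

  resolve_order <- function(sym, i, j) {
    if (!is.na(sym)) {
      switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
             stop("unsupported bond symbol '", sym, "'"))
    } else if (aromatic[i] && aromatic[j]) 1.5 else 1
  }

  add_bond <- function(i, j, sym) {
    if (i == j) stop("SMILES ring closure bonds an atom to itself")
    if (any(b_a1 == min(i, j) & b_a2 == max(i, j)))
      stop("duplicate bond between atoms ", i, " and ", j)
    ord <- resolve_order(sym, i, j)
    b_a1[length(b_a1) + 1L] <<- min(i, j)
    b_a2[length(b_a2) + 1L] <<- max(i, j)
    b_order[length(b_order) + 1L] <<- ord
    b_arom[length(b_arom) + 1L] <<- (ord == 1.5)
    invisible(ord)
  }

  connect <- function(cur) {
    if (prev > 0L) {
      add_bond(prev, cur, pending)
      nbrs[[prev]] <<- c(nbrs[[prev]], cur)
      nbrs[[cur]] <<- c(nbrs[[cur]], prev)
    } else if (!is.na(pending)) {
      stop("bond symbol with no preceding atom at position ", pos)
    }
    pending <<- NA_character_
    prev <<- cur
  }

  ring_event <- function(label) {
    key <- as.character(label)
    if (prev == 0L) stop("ring-closure digit before any atom")
    if (is.null(open_rings[[key]])) {
      nbrs[[prev]] <<- c(nbrs[[prev]], -label)  # placeholder until matched
      open_rings[[key]] <<- list(atom = prev, pos = length(nbrs[[prev]]),
                                 sym = pending)
    } else {
      op <- open_rings[[key]]
      sym <- if (!is.na(pending)) pending else op$sym
      if (!is.na(pending) && !is.na(op$sym) && pending != op$sym)
        stop("conflicting bond symbols on ring closure ", key)
      add_bond(op$atom, prev, sym)
      nbrs[[op$atom]][op$pos] <<- prev
      nbrs[[prev]] <<- c(nbrs[[prev]], op$atom)
      open_rings[[key]] <<- NULL
    }
    pending <<- NA_character_
  }

  bracket_re <- "^\\[([0-9]+)?([A-Za-z][a-z]?|\\*)(@@?)?(H[0-9]*)?([+-][0-9]+|\\++|-+)?(:[0-9]+)?\\]"

  while (pos <= len) {
    ch <- substr(s, pos, pos)

    if (ch == "[") {
      m <- regexec(bracket_re, substr(s, pos, len))[[1]]
      if (m[1] == -1L) stop("malformed bracket atom at position ", pos,
                            " in '", s, "'")
      parts <- regmatches(substr(s, pos, len), list(m))[[1]]
      if (nzchar(parts[2]))
        stop("isotope labels are not supported (position ", pos, ")")
      sym <- parts[3]
      if (sym == "*") stop("wildcard atoms are not supported")
      arom <- substr(sym, 1, 1) %in% letters
      el <- if (arom) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      if (!el %in% names(.ATOMIC_NUMBER))
        stop("unknown element '", el, "' at position ", pos,
             " in '", s, "'")
      chi <- parts[4]
      hstr <- parts[5]
      h <- if (!nzchar(hstr)) 0L
      else if (hstr == "H") 1L
      else as.integer(substr(hstr, 2, nchar(hstr)))
      cstr <- parts[6]
      chg <- if (!nzchar(cstr)) 0L
      else if (grepl("^\\++$", cstr)) nchar(cstr)
      else if (grepl("^-+$", cstr)) -nchar(cstr)
      else as.integer(cstr)
      mp <- if (nzchar(parts[7])) {
        as.integer(substr(parts[7], 2, nchar(parts[7])))
      } else 0L
      cur <- add_atom(el, arom, chg, h, mp, chi)
      connect(cur)
      if (h > 0L) nbrs[[cur]] <- c(nbrs[[cur]], rep(0L, h))
      pos <- pos + attr(m, "match.length")[1]

    } else if (ch %in% c("-", "=", "#", ":")) {
      if (!is.na(pending)) stop("two consecutive bond symbols at position ", pos)
      pending <- ch
      pos <- pos + 1L

    } else if (ch %in% c("/", "\\")) {
      stop("directional (E/Z) bond symbols are not supported")

    } else if (ch == "(") {
      if (prev == 0L) stop("branch opened before any atom")
      stack <- c(stack, prev)
      pos <- pos + 1L

    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' at position ", pos)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L

    } else if (grepl("^[0-9]$", ch)) {
      ring_event(as.integer(ch))
      pos <- pos + 1L

    } else if (ch == "%") {
      lab <- substr(s, pos + 1L, pos + 2L)
      if (!grepl("^[0-9]{2}$", lab))
        stop("'%' ring label must be two digits (position ", pos, ")")
      ring_event(as.integer(lab))
      pos <- pos + 3L

    } else if (ch == ".") {
      stop("disconnected (dot) SMILES are not supported")

    } else {
      two <- substr(s, pos, pos + 1L)
      if (two %in% c("Cl", "Br")) {
        cur <- add_atom(two, FALSE, 0L, NA_integer_, 0L, "")
        connect(cur)
        pos <- pos + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        cur <- add_atom(ch, FALSE, 0L, NA_integer_, 0L, "")
        connect(cur)
        pos <- pos + 1L
      } else if (ch %in% .AROMATIC_SUBSET) {
        cur <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, "")
        connect(cur)
        pos <- pos + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", pos,
             " in '", s, "'")
      }
    }
  }

  if (length(stack) > 0L) stop("unclosed branch '(' in '", s, "'")
  if (length(open_rings) > 0L)
    stop("unclosed ring label(s) ", paste(names(open_rings), collapse = ", "),
         " in '", s, "'")
  if (n == 0L) stop("no atoms parsed from '", s, "'")

  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_order,
                      aromatic = b_arom)
  atoms <- data.frame(element = element, aromatic = aromatic,
                      charge = charge, hcount = hq, map = map,
                      chiral = chiral, stringsAsFactors = FALSE)

  mol <- structure(
    list(atoms = atoms, bonds = bonds, stereo_nbrs = nbrs, smiles = smiles),
    class = "chk_mol"
  )
  mol$atoms$hcount <- .assign_implicit_h(mol)
  .check_valence(mol)
  .check_connected(mol)
  mol
}

# bond-order sum per atom (aromatic bonds count 1.5)
.order_sums <- function(mol) {
  v <- numeric(nrow(mol$atoms))
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      v[b$a1[k]] <- v[b$a1[k]] + b$order[k]
      v[b$a2[k]] <- v[b$a2[k]] + b$order[k]
    }
  }
  v
}

# number of explicit connections per atom
.degrees <- function(mol) {
  tab <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = nrow(mol$atoms))
  as.integer(tab)
}

.assign_implicit_h <- function(mol) {
  at <- mol$atoms
  osum <- .order_sums(mol)
  deg <- .degrees(mol)
  h <- at$hcount
  for (i in seq_len(nrow(at))) {
    if (!is.na(h[i])) next  # bracket atom: explicit count
    el <- at$element[i]
    if (at$aromatic[i]) {
      # organic-subset aromatic atom: carbon carries one H when two-connected;
      # aromatic N/O/S contribute lone pairs and carry none (pyrrole N must be
      # written [nH])
      h[i] <- if (el == "C") max(0L, 3L - deg[i]) else 0L
      next
    }
    base <- .BASE_VALENCE[[el]]
    if (is.null(base)) stop("element '", el, "' needs a bracket atom")
    val <- base + at$charge[i]
    cand <- c(val, .ALT_VALENCE[[el]] + at$charge[i])
    cand <- cand[cand >= osum[i]]
    if (length(cand) == 0L)
      stop("valence of atom ", i, " (", el, ") exceeded in '", mol$smiles, "'")
    h[i] <- as.integer(cand[1] - osum[i])
  }
  as.integer(h)
}

.check_valence <- function(mol) {
  at <- mol$atoms
  tot <- .order_sums(mol) + at$hcount
  for (i in seq_len(nrow(at))) {
    mx <- unname(.MAX_VALENCE[at$element[i]])
    if (is.na(mx)) next  # element without a registered cap: trust the bracket
    mx <- mx + max(0L, at$charge[i])
    if (tot[i] > mx + 0.5)
      stop("atom ", i, " (", at$element[i], ") exceeds valence ", mx,
           " in '", mol$smiles, "'")
    if (at$aromatic[i] && sum(mol$bonds$aromatic &
                              (mol$bonds$a1 == i | mol$bonds$a2 == i)) < 2L)
      stop("aromatic atom ", i, " is not in an aromatic ring in '",
           mol$smiles, "'")
  }
  invisible(TRUE)
}

.check_connected <- function(mol) {
  if (nrow(mol$atoms) == 1L) return(invisible(TRUE))
  g <- .mol_igraph(mol)
  if (igraph::components(g)$no != 1L)
    stop("molecule is disconnected: '", mol$smiles, "'")
  invisible(TRUE)
}

.mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = mol$bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

#' @export
print.chk_mol <- function(x, ...) {
  cat("<chk_mol> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds: ",
      x$smiles, "\n", sep = "")
  invisible(x)
}

#' Number of atoms / bonds in a molecule
#'
#' @param mol A `chk_mol` object from [parse_smiles()].
#' @return Integer count of heavy atoms (`mol_natoms`) or bonds
#'   (`mol_nbonds`).
#' @export
mol_natoms <- function(mol) nrow(mol$atoms)

#' @rdname mol_natoms
#' @export
mol_nbonds <- function(mol) nrow(mol$bonds)
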