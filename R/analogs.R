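# -- L / D / peptoid analog generation ----------------------------------------
#
# Peptoid analogs move the side chain from the alpha carbon to the backbone
# nitrogen (an N-substituted glycine), so an L residue and its peptoid
# analog are constitutional isomers with identical molecular formulas.
# Proline and glycine have no peptoid analog and are excluded from the
# random-sequence alphabet.

.AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
               Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
               K = "Lys", L = "Leu", M = "Met", F = "Phe", P = "Pro",
               S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Alphabet of canonical residues with peptoid analogs
#'
#' The 18 canonical one-letter tokens excluding proline and glycine,
#' which have no peptoid analog.
#'
#' @return Character vector of length 18.
#' @export
peptoid_alphabet <- function() setdiff(names(.AA_THREE), c("P", "G"))

#' Random L-peptide sequences
#'
#' Draws `n` sequences with lengths uniform on `[min_len, max_len]` and
#' residues uniform over the 18-letter alphabet of [peptoid_alphabet()]
#' (canonical residues excluding P and G).  Reproducible under `seed`.
#'
#' @param n Number of sequences.
#' @param min_len,max_len Length bounds (defaults 5 and 30).
#' @param seed Optional integer seed.
#' @return Character vector of `n` sequence strings.
#' @examples
#' random_l_sequences(3, 5, 8, seed = 1)
#' @export
random_l_sequences <- function(n, min_len = 5L, max_len = 30L, seed = NULL) {
  if (n <= 0L) stop("n must be positive")
  if (min_len > max_len) stop("min_len must not exceed max_len")
  if (!is.null(seed)) set.seed(seed)
  alpha <- peptoid_alphabet()
  lens <- seq.int(min_len, max_len)[sample.int(max_len - min_len + 1L, n,
                                               replace = TRUE)]
  vapply(lens, function(L)
    paste(sample(alpha, L, replace = TRUE), collapse = ""), character(1))
}

#' Translate an L-sequence to its D analog
#'
#' Lowercases every canonical token (the library's D-isomer convention).
#'
#' @param seq A sequence string of canonical uppercase tokens.
#' @return The all-D sequence string.
#' @examples
#' to_d("AK")
#' @export
to_d <- function(seq) {
  tokens <- strsplit(seq, "")[[1]]
  bad <- setdiff(tokens, setdiff(names(.AA_THREE), "G"))
  if (length(bad))
    stop("token(s) without a D-isomer: ", paste(bad, collapse = ", "))
  tolower(seq)
}

#' Translate an L-sequence to its peptoid analog
#'
#' Replaces each canonical token X by the library's `{NXxx}` peptoid
#' analog token.  Proline and glycine have no analog and raise an error.
#'
#' @param seq A sequence string of canonical uppercase tokens.
#' @param library A `residue_library` containing the `{NXxx}` entries.
#' @return The peptoid sequence string.
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' to_peptoid("A", lib)
#' @export
to_peptoid <- function(seq, library) {
  tokens <- strsplit(seq, "")[[1]]
  out <- character(length(tokens))
  for (i in seq_along(tokens)) {
    t <- tokens[i]
    if (!t %in% names(.AA_THREE))
      stop("not a canonical token: '", t, "'")
    ptok <- paste0("{N", .AA_THREE[[t]], "}")
    if (!has_token(library, ptok))
      stop("residue '", t, "' has no peptoid analog in the library")
    out[i] <- ptok
  }
  paste(out, collapse = "")
}

#' Generate L/D/peptoid analog triples
#'
#' Emulates the random-sequence design used to probe how atom-level
#' models organize stereo- and constitutional isomers: random L-sequences
#' (no P/G) are translated into all-D and all-peptoid versions.  The three
#' members of each triple assemble to molecules with identical molecular
#' formulas; L and D are enantiomers and the peptoid is a distinct
#' constitutional isomer.
#'
#' @inheritParams random_l_sequences
#' @param library A `residue_library` with the peptoid entries.
#' @return A data frame with columns `l_seq`, `d_seq`, `peptoid_seq`.
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' analog_triples(2, 5, 8, seed = 7, library = lib)
#' @export
analog_triples <- function(n = 100L, min_len = 5L, max_len = 30L,
                           seed = NULL, library = load_default_library(validate = FALSE)) {
  l <- random_l_sequences(n, min_len, max_len, seed)
  data.frame(
    l_seq = l,
    d_seq = vapply(l, to_d, character(1), USE.NAMES = FALSE),
    peptoid_seq = vapply(l, to_peptoid, character(1),
                         library = library, USE.NAMES = FALSE)
  )
}
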