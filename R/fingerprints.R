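# -- fingerprints and baseline encodings --------------------------------------

.ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' Morgan (circular) fingerprint of an assembled peptide
#'
#' Circular-substructure fingerprint computed with OpenBabel's ECFP
#' implementation (radius r uses the ECFP(2r) plugin) and folded to
#' `n_bits` by index.  Deterministic for a fixed molecule and
#' configuration, and invariant to how the SMILES is written.
#'
#' @param peptide An `assembled_peptide` (or a SMILES string).
#' @param n_bits Fingerprint length (default 2048).
#' @param radius Circular neighborhood radius (default 2, the
#'   ECFP4-equivalent).
#' @return Integer 0/1 vector of length `n_bits`.
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' fp <- morgan_fingerprint(assemble_peptide("AG", lib))
#' length(fp)
#' @export
morgan_fingerprint <- function(peptide, n_bits = 2048L, radius = 2L) {
  stopifnot(n_bits >= 1L, radius >= 0L)
  if (radius > 5L)
    stop("radius > 5 is not supported (no ECFP", 2L * radius, " plugin)")
  smiles <- if (inherits(peptide, "assembled_peptide")) peptide$smiles
  else peptide
  raw <- ChemmineOB::fingerprint_OB(.ob_mol(smiles),
                                    paste0("ECFP", 2L * radius))
  if (is.matrix(raw)) raw <- raw[1, ]
  raw <- as.integer(raw)
  folded <- integer(n_bits)
  on_bits <- which(raw == 1L) - 1L
  folded[(on_bits %% n_bits) + 1L] <- 1L
  folded
}

#' MACCS structural keys of an assembled peptide
#'
#' The standard 166-key MACCS dictionary, computed with OpenBabel's MACCS
#' SMARTS definitions (the trailing padding of OpenBabel's 256-bit word
#' output is verified empty and dropped).
#'
#' @inheritParams morgan_fingerprint
#' @return Integer 0/1 vector of length 166, with attribute `n_bits`
#'   recording the key-set length.
#' @export
maccs_keys <- function(peptide) {
  smiles <- if (inherits(peptide, "assembled_peptide")) peptide$smiles
  else peptide
  raw <- ChemmineOB::fingerprint_OB(.ob_mol(smiles), "MACCS")
  if (is.matrix(raw)) raw <- raw[1, ]
  raw <- as.integer(raw)
  if (length(raw) > 166L && any(raw[167:length(raw)] == 1L))
    stop("unexpected MACCS bits beyond key 166")
  keys <- raw[seq_len(166L)]
  attr(keys, "n_bits") <- 166L
  keys
}

#' One-hot sequence encoding
#'
#' Position-by-token indicator matrix: row t is the indicator of token t
#' over `alphabet`; rows beyond the sequence length are zero padding.
#'
#' @param seq A `tokenized_sequence` or character vector of tokens.
#' @param alphabet Character vector of allowed tokens (unique).
#' @param max_len Number of rows (maximum sequence length).
#' @param flatten Return the matrix flattened row-wise to a vector.
#' @return A `max_len` x `length(alphabet)` 0/1 matrix (or its row-wise
#'   flattening).
#' @examples
#' onehot_encode(c("A", "G"), alphabet = c("A", "G"), max_len = 3)
#' @export
onehot_encode <- function(seq, alphabet, max_len, flatten = FALSE) {
  tokens <- if (inherits(seq, "tokenized_sequence")) seq$tokens else seq
  if (length(alphabet) == 0L) stop("empty alphabet")
  if (anyDuplicated(alphabet)) stop("alphabet tokens must be unique")
  if (length(tokens) > max_len)
    stop("sequence length ", length(tokens), " exceeds max_len ", max_len)
  missing <- setdiff(tokens, alphabet)
  if (length(missing))
    stop("token(s) outside alphabet: ", paste(missing, collapse = ", "))
  M <- matrix(0L, nrow = max_len, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  for (t in seq_along(tokens)) M[t, match(tokens[t], alphabet)] <- 1L
  if (flatten) as.integer(t(M)) else M
}
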