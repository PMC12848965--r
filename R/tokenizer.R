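# -- sequence tokenizer -------------------------------------------------------

#' Tokenize a peptide sequence string
#'
#' Scans the sequence left to right: `{` opens a multi-character token
#' closed by the next `}`; any other character is a single-character token.
#' Every token must resolve in `library`; tokens classified `n_cap` /
#' `c_cap` are only legal at the first / last position, and cyclic
#' sequences may not carry caps.  Whitespace is rejected rather than
#' stripped, so data errors in batch files surface instead of being
#' silently normalized.
#'
#' @param sequence A sequence string, e.g. `"ac{Aib}Kw"` or `"AGLW"`.
#' @param library A `residue_library`.
#' @param cyclic `TRUE` for a head-to-tail cycle.
#' @return A `tokenized_sequence`: list with `tokens` (character vector),
#'   `topology` (`"linear"` or `"head_to_tail_cyclic"`), `n_cap`, `c_cap`
#'   (token or `NA`), and `sequence` (the input string).
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' tokenize_sequence("A{Aib}kW", lib)$tokens
#' @export
tokenize_sequence <- function(sequence, library, cyclic = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("[[:space:]]", sequence))
    stop("sequence contains whitespace: '", sequence, "'")

  chars <- strsplit(sequence, "")[[1]]
  tokens <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "{") {
      j <- i + 1L
      body <- character()
      while (j <= length(chars) && !(chars[j] %in% c("{", "}"))) {
        body <- c(body, chars[j]); j <- j + 1L
      }
      if (j > length(chars) || chars[j] == "{")
        stop("unbalanced or nested brace starting at position ", i,
             " in '", sequence, "'")
      if (length(body) == 0L)
        stop("empty braces at position ", i, " in '", sequence, "'")
      tokens <- c(tokens, paste0("{", paste(body, collapse = ""), "}"))
      i <- j + 1L
    } else if (ch == "}") {
      stop("unbalanced '}' at position ", i, " in '", sequence, "'")
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }

  missing <- !has_token(library, tokens)
  if (any(missing)) {
    k <- which(missing)[1]
    stop("token '", tokens[k], "' (position ", k,
         ") is not in the residue library")
  }

  cls <- vapply(tokens, function(t) library[[t]]$class, character(1))
  k <- length(tokens)
  cap_pos <- which(cls %in% c("n_cap", "c_cap"))
  for (p in cap_pos) {
    if (cls[p] == "n_cap" && p != 1L)
      stop("n_cap token '", tokens[p], "' at interior position ", p)
    if (cls[p] == "c_cap" && p != k)
      stop("c_cap token '", tokens[p], "' at interior position ", p)
  }

  if (cyclic) {
    if (length(cap_pos))
      stop("cyclic sequences cannot carry cap tokens")
    if (k < 2L) stop("cyclic sequences need at least 2 residues")
  }

  structure(
    list(tokens = unname(tokens),
         topology = if (cyclic) "head_to_tail_cyclic" else "linear",
         n_cap = if (k > 0L && cls[1] == "n_cap") tokens[1] else NA_character_,
         c_cap = if (k > 0L && cls[k] == "c_cap") tokens[k] else NA_character_,
         sequence = sequence),
    class = "tokenized_sequence"
  )
}

#' @export
print.tokenized_sequence <- function(x, ...) {
  cat("<tokenized_sequence> ", paste(x$tokens, collapse = " "),
      " [", x$topology, "]\n", sep = "")
  invisible(x)
}

#' Reassemble the sequence string from its tokens
#'
#' Inverse of [tokenize_sequence()]: concatenating the tokens (braces
#' restored) reproduces the input string exactly.
#'
#' @param x A `tokenized_sequence` or a character vector of tokens.
#' @return The sequence string.
#' @export
detokenize <- function(x) {
  tokens <- if (inherits(x, "tokenized_sequence")) x$tokens else x
  paste(tokens, collapse = "")
}
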