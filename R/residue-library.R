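# -- residue library ----------------------------------------------------------
#
# Monomers are defined in CHUCKLES order (N-terminus, alpha carbon,
# C-terminus) so that peptides assemble by string concatenation.  Atom map 1
# marks the backbone nitrogen (first atom written), atom map 2 the
# C-terminal carbonyl carbon, and every residue that donates a C-terminus
# ends in the free-acid tail "(=O)O".  N-caps carry map 2 only, C-caps
# map 1 only.

.RESIDUE_CLASSES <- c("canonical", "d_isomer", "ncaa", "peptoid",
                      "n_cap", "c_cap", "polymer")
.CHIRALITY_LEVELS <- c("L", "D", "achiral")

.TOKEN_RE <- "^([A-Z]|[a-z]|\\{[^{}]+\\})$"

#' Construct a residue entry
#'
#' @param token Residue symbol: one uppercase letter (L-amino acid), one
#'   lowercase letter (D-amino acid), or `{Abc}` (noncanonical residues and
#'   modifications).
#' @param smiles The monomer SMILES in CHUCKLES atom order with terminal
#'   atom maps.
#' @param chirality `"L"`, `"D"` or `"achiral"`.
#' @param class One of `r paste0('"', .RESIDUE_CLASSES, '"', collapse = ", ")`.
#' @param name Human-readable residue name.
#' @param cas Optional CAS registry number.
#' @param alpha_cip Optional expected CIP code of the alpha carbon
#'   (`"R"`, `"S"` or `"none"`), used by [validate_entry()].
#' @return A `residue_entry` object.
#' @export
residue_entry <- function(token, smiles, chirality = "achiral",
                          class = "ncaa", name = token, cas = NA_character_,
                          alpha_cip = NA_character_) {
  chirality <- match.arg(chirality, .CHIRALITY_LEVELS)
  class <- match.arg(class, .RESIDUE_CLASSES)
  structure(
    list(token = token, name = name, smiles = smiles, chirality = chirality,
         class = class, cas = cas, alpha_cip = alpha_cip),
    class = "residue_entry"
  )
}

#' @export
print.residue_entry <- function(x, ...) {
  cat("<residue_entry> ", x$token, " (", x$name, "): ", x$smiles,
      " [", x$chirality, ", ", x$class, "]\n", sep = "")
  invisible(x)
}

.new_library <- function(df, source) {
  if (anyDuplicated(df$token))
    stop("duplicate token(s): ",
         paste(unique(df$token[duplicated(df$token)]), collapse = ", "))
  rownames(df) <- NULL
  structure(list(entries = df, source = source), class = "residue_library")
}

#' @export
print.residue_library <- function(x, ...) {
  cat("<residue_library> ", nrow(x$entries), " entries (",
      x$source, ")\n", sep = "")
  print(table(x$entries$class))
  invisible(x)
}

#' @export
length.residue_library <- function(x) nrow(x$entries)

#' Look up a residue entry by token
#'
#' @param x A `residue_library`.
#' @param token A residue token string.
#' @export
`[[.residue_library` <- function(x, token) {
  i <- match(token, x$entries$token)
  if (is.na(i)) stop("token '", token, "' not in library")
  e <- x$entries[i, ]
  residue_entry(e$token, e$smiles, e$chirality, e$class, e$name,
                e$cas, e$alpha_cip)
}

#' Tokens defined in a residue library
#'
#' @param library A `residue_library`.
#' @return Character vector of tokens in library order.
#' @export
library_tokens <- function(library) library$entries$token

#' Test whether a token is defined
#'
#' @inheritParams library_tokens
#' @param token Token string(s).
#' @export
has_token <- function(library, token) token %in% library$entries$token

# ---------------------------------------------------------------------------

#' Load the packaged default residue library
#'
#' The default library holds 157 validated monomers: the 20 canonical
#' L-amino acids, their 19 D-isomers, peptoid analogs of the canonical side
#' chains (proline and glycine excepted, having no peptoid analog),
#' N-methyl variants, common noncanonical amino acids in both L and D
#' forms, end caps (acetyl, formyl, benzoyl, amide, N-methylamide,
#' N,N-dimethylamide) and PEG-type polymer units.
#'
#' @param validate Re-validate every entry on load (default `TRUE`).
#' @return A `residue_library` with 157 entries.
#' @examples
#' lib <- load_default_library()
#' length(lib)
#' lib[["A"]]
#' @export
load_default_library <- function(validate = TRUE) {
  path <- system.file("extdata", "residue_library.csv", package = "chuckles",
                      mustWork = TRUE)
  lib <- load_residue_library(path, validate = validate)
  lib$source <- "default"
  lib
}

.COLUMN_ALIASES <- list(
  token = c("token"),
  name = c("name"),
  smiles = c("smiles", "smiles (chuckles)", "chuckles smiles",
             "chuckles_smiles", "smiles_chuckles"),
  chirality = c("chirality"),
  class = c("class", "residue class", "residue_class"),
  cas = c("cas", "cas number"),
  alpha_cip = c("alphacip", "alpha_cip", "alpha cip"),
  reference_canonical = c("reference_canonical", "referencecanonical",
                          "canonical", "reference canonical")
)

.match_columns <- function(nms) {
  norm <- tolower(trimws(nms))
  out <- stats::setNames(rep(NA_integer_, length(.COLUMN_ALIASES)),
                         names(.COLUMN_ALIASES))
  for (field in names(.COLUMN_ALIASES)) {
    hit <- which(norm %in% .COLUMN_ALIASES[[field]])
    if (length(hit)) out[field] <- hit[1]
  }
  out
}

#' Load a residue library from CSV or XLSX
#'
#' The table must contain at least a token column and a CHUCKLES SMILES
#' column; header names are matched case-insensitively after trimming
#' (`Token`, `Name`, `SMILES (CHUCKLES)`, `Chirality`, `Class`, `CAS`,
#' `AlphaCIP`).  Missing chirality is inferred from token case (uppercase
#' letter: L; lowercase letter: D; braces: achiral), and a missing class
#' likewise (canonical / d_isomer / ncaa).  Row order is preserved.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param validate Validate every row (default `TRUE`); the error message
#'   of a failing row names the row number, token and failed check.
#' @return A `residue_library`.
#' @export
load_residue_library <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("library file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  } else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX libraries requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, sheet = 1,
                                     col_types = "text"))
  } else {
    stop("unsupported library file type '.", ext, "' (use CSV or XLSX)")
  }
  cols <- .match_columns(names(raw))
  if (is.na(cols["token"])) stop("library file lacks a 'Token' column")
  if (is.na(cols["smiles"]))
    stop("library file lacks a 'SMILES (CHUCKLES)' column")

  get_col <- function(field, default = NA_character_) {
    if (is.na(cols[field])) rep(default, nrow(raw))
    else {
      v <- trimws(as.character(raw[[cols[field]]]))
      v[!nzchar(v) | is.na(v)] <- default
      v
    }
  }

  token <- trimws(as.character(raw[[cols["token"]]]))
  df <- data.frame(
    token = token,
    name = get_col("name"),
    smiles = trimws(as.character(raw[[cols["smiles"]]])),
    chirality = get_col("chirality"),
    class = get_col("class"),
    cas = get_col("cas"),
    alpha_cip = get_col("alpha_cip"),
    reference_canonical = get_col("reference_canonical"),
    stringsAsFactors = FALSE
  )
  df$name[is.na(df$name)] <- df$token[is.na(df$name)]
  # infer chirality from token case, but only for entries that actually
  # carry a stereocenter tag (so e.g. glycine stays achiral)
  has_stereo <- grepl("@", df$smiles, fixed = TRUE)
  infer_chir <- ifelse(grepl("^[A-Z]$", df$token) & has_stereo, "L",
                       ifelse(grepl("^[a-z]$", df$token) & has_stereo,
                              "D", "achiral"))
  df$chirality[is.na(df$chirality)] <- infer_chir[is.na(df$chirality)]
  infer_class <- ifelse(grepl("^[A-Z]$", df$token), "canonical",
                        ifelse(grepl("^[a-z]$", df$token), "d_isomer", "ncaa"))
  df$class[is.na(df$class)] <- infer_class[is.na(df$class)]

  if (anyDuplicated(df$token))
    stop("duplicate token(s) in library file: ",
         paste(unique(df$token[duplicated(df$token)]), collapse = ", "))

  lib <- .new_library(df, source = "custom")
  if (validate) {
    for (i in seq_len(nrow(df))) {
      rep <- validate_entry(lib[[df$token[i]]])
      if (!all(rep$pass)) {
        bad <- rep[!rep$pass, ]
        stop("library row ", i, " (token '", df$token[i], "') failed ",
             "validation: ", paste(bad$check, "-", bad$detail,
                                   collapse = "; "))
      }
    }
  }
  lib
}

#' Write a residue library to CSV
#'
#' Writes the standard column layout; the result round-trips through
#' [load_residue_library()] entry-by-entry.
#'
#' @param library A `residue_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_residue_library <- function(library, path) {
  df <- library$entries
  out <- data.frame(
    Token = df$token, Name = df$name, `SMILES (CHUCKLES)` = df$smiles,
    Chirality = df$chirality, Class = df$class, CAS = df$cas,
    AlphaCIP = df$alpha_cip, ReferenceCanonical = df$reference_canonical,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Validate a residue entry against the CHUCKLES contract
#'
#' Runs the per-entry checks and reports pass/fail for each rather than
#' raising: token grammar; SMILES parseability; atom-map placement (map 1
#' on the first-written nitrogen, map 2 on a carbonyl carbon, present or
#' absent according to residue class); the C-terminal `"(=O)O"` tail;
#' agreement of the computed alpha-carbon CIP code with `alpha_cip` when
#' set; and a stereochemistry round trip (parse, rewrite, reparse,
#' canonical forms equal).
#'
#' @param entry A `residue_entry`.
#' @return A data frame of class `validation_report` with columns `check`,
#'   `pass`, `detail`; attribute `ok` is `TRUE` when every check passed.
#' @examples
#' e <- residue_entry("A", "[NH2:1][C@@H](C)[C:2](=O)O", "L", "canonical",
#'                    alpha_cip = "S")
#' validate_entry(e)
#' @export
validate_entry <- function(entry) {
  checks <- character(); pass <- logical(); detail <- character()
  note <- function(check, ok, why = "") {
    checks[length(checks) + 1L] <<- check
    pass[length(pass) + 1L] <<- ok
    detail[length(detail) + 1L] <<- why
  }

  note("token_grammar", grepl(.TOKEN_RE, entry$token),
       if (!grepl(.TOKEN_RE, entry$token))
         "token must be one uppercase letter, one lowercase letter, or {...}"
       else "")

  mol <- tryCatch(parse_smiles(entry$smiles), error = function(e) e)
  if (inherits(mol, "error")) {
    note("parse", FALSE, conditionMessage(mol))
    rep <- data.frame(check = checks, pass = pass, detail = detail)
    class(rep) <- c("validation_report", "data.frame")
    attr(rep, "ok") <- FALSE
    return(rep)
  }
  note("parse", TRUE)

  map1 <- which(mol$atoms$map == 1L)
  map2 <- which(mol$atoms$map == 2L)
  need1 <- entry$class != "n_cap"
  need2 <- entry$class != "c_cap"

  if (need1) {
    ok1 <- length(map1) == 1L && mol$atoms$element[map1[1]] == "N" &&
      map1[1] == 1L
    note("map1_nitrogen_first", ok1,
         if (!ok1) "exactly one map-1 atom required: a nitrogen, written first"
         else "")
  } else {
    note("map1_absent", length(map1) == 0L,
         if (length(map1)) "n_cap entries must not carry map 1" else "")
  }

  if (need2) {
    ok2 <- length(map2) == 1L && mol$atoms$element[map2[1]] == "C" &&
      .is_carbonyl(mol, map2[1])
    note("map2_carbonyl_carbon", ok2,
         if (!ok2) "exactly one map-2 atom required: the carbonyl carbon"
         else "")
    tail_ok <- grepl("\\(=O\\)O$", entry$smiles)
    note("acid_tail", tail_ok,
         if (!tail_ok) "CHUCKLES string must end with '(=O)O'" else "")
  } else {
    note("map2_absent", length(map2) == 0L,
         if (length(map2)) "c_cap entries must not carry map 2" else "")
  }

  if (!is.na(entry$alpha_cip) && need2 && length(map2) == 1L) {
    alpha <- .alpha_carbon(mol, map2[1])
    cip <- assign_cip(mol)
    got <- if (is.na(alpha)) NA_character_ else cip[alpha]
    if (entry$alpha_cip == "none") {
      note("alpha_cip", is.na(got),
           if (!is.na(got)) paste0("alpha carbon has CIP ", got,
                                   " but 'none' expected") else "")
    } else {
      note("alpha_cip", !is.na(got) && got == entry$alpha_cip,
           if (is.na(got) || got != entry$alpha_cip)
             paste0("alpha CIP ", ifelse(is.na(got), "undefined", got),
                    " != expected ", entry$alpha_cip) else "")
    }
  }

  rt <- tryCatch({
    rewritten <- write_smiles(mol)
    identical(canonical_smiles(entry$smiles), canonical_smiles(rewritten))
  }, error = function(e) FALSE)
  note("stereo_round_trip", isTRUE(rt),
       if (!isTRUE(rt)) "parse -> write -> parse changed the canonical form"
       else "")

  rep <- data.frame(check = checks, pass = pass, detail = detail)
  class(rep) <- c("validation_report", "data.frame")
  attr(rep, "ok") <- all(pass)
  rep
}

.is_carbonyl <- function(mol, i) {
  b <- mol$bonds
  inc <- which(b$a1 == i | b$a2 == i)
  for (k in inc) {
    j <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
    if (mol$atoms$element[j] == "O" && b$order[k] == 2) return(TRUE)
  }
  FALSE
}

# the alpha carbon: the non-oxygen neighbor of the map-2 carbonyl carbon
.alpha_carbon <- function(mol, map2_atom) {
  b <- mol$bonds
  inc <- which(b$a1 == map2_atom | b$a2 == map2_atom)
  for (k in inc) {
    j <- if (b$a1[k] == map2_atom) b$a2[k] else b$a1[k]
    if (mol$atoms$element[j] != "O") return(j)
  }
  NA_integer_
}

#' L/D residue flag
#'
#' Two-element indicator distinguishing L- from D-residues in hierarchical
#' (residue-level) graph models: `(1, 0)` for L, `(0, 1)` for D, and
#' `(0, 0)` for achiral residues (glycine, peptoids, caps, polymer units),
#' which belong to neither class.
#'
#' @param entry A `residue_entry`.
#' @return Integer vector of length 2.
#' @examples
#' lib <- load_default_library(validate = FALSE)
#' residue_flag(lib[["F"]]) # 1 0
#' residue_flag(lib[["f"]]) # 0 1
#' @export
residue_flag <- function(entry) {
  switch(entry$chirality,
         L = c(1L, 0L),
         D = c(0L, 1L),
         achiral = c(0L, 0L))
}
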