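# -- batch processing ---------------------------------------------------------

#' Batch configuration
#'
#' Bundles the options of a batch run.  `outputs` selects any subset of
#' `"smiles"`, `"graph"`, `"morgan"`, `"maccs"`, `"onehot"`.
#'
#' @param input Path to a CSV with a `sequence` column and an optional
#'   logical `cyclic` column.
#' @param out_dir Output directory (created if missing).
#' @param outputs Character vector of requested outputs.
#' @param library_path Optional residue library (CSV/XLSX); default
#'   library when `NULL`.
#' @param sequence_col,cyclic_col Column names in `input`.
#' @param include_chirality,directed_duplication Graph options, see
#'   [build_graph()].
#' @param morgan_bits,morgan_radius Morgan options, see
#'   [morgan_fingerprint()].
#' @param onehot_max_len Row count of one-hot encodings; defaults to the
#'   longest sequence in the batch.
#' @param seed Optional integer seed set before processing.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, outputs = "smiles",
                       library_path = NULL,
                       sequence_col = "sequence", cyclic_col = "cyclic",
                       include_chirality = FALSE,
                       directed_duplication = TRUE,
                       morgan_bits = 2048L, morgan_radius = 2L,
                       onehot_max_len = NULL, seed = NULL) {
  if (length(outputs) == 0L) stop("at least one output must be requested")
  outputs <- match.arg(outputs,
                       c("smiles", "graph", "morgan", "maccs", "onehot"),
                       several.ok = TRUE)
  structure(
    list(input = input, out_dir = out_dir, outputs = outputs,
         library_path = library_path, sequence_col = sequence_col,
         cyclic_col = cyclic_col, include_chirality = include_chirality,
         directed_duplication = directed_duplication,
         morgan_bits = morgan_bits, morgan_radius = morgan_radius,
         onehot_max_len = onehot_max_len, seed = seed),
    class = "run_config"
  )
}

#' Run a batch of sequences through the pipeline
#'
#' Processes each row of the input CSV with per-row fault isolation: a
#' failing sequence is recorded in the report (with its offending token
#' or parse error) and does not abort the batch.  Outputs are written to
#' `config$out_dir`; re-running an identical configuration reproduces the
#' files byte for byte.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `n_ok`, `n_failed`, `failures`
#'   (data frame: `row`, `sequence`, `error`) and `files` (paths
#'   written), invisibly printed.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input)) stop("unreadable input: ", config$input)
  lib <- if (is.null(config$library_path)) load_default_library(validate = FALSE)
  else load_residue_library(config$library_path)
  if (!is.null(config$seed)) set.seed(config$seed)

  tab <- utils::read.csv(config$input, stringsAsFactors = FALSE)
  if (!config$sequence_col %in% names(tab))
    stop("input lacks a '", config$sequence_col, "' column")
  seqs <- as.character(tab[[config$sequence_col]])
  cyc <- if (config$cyclic_col %in% names(tab))
    as.logical(tab[[config$cyclic_col]]) else rep(FALSE, length(seqs))
  cyc[is.na(cyc)] <- FALSE

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  peptides <- vector("list", length(seqs))
  errors <- rep(NA_character_, length(seqs))
  for (i in seq_along(seqs)) {
    peptides[i] <- list(tryCatch(
      assemble_peptide(seqs[i], lib, cyclic = cyc[i]),
      error = function(e) { errors[i] <<- conditionMessage(e); NULL }))
  }
  ok <- !vapply(peptides, is.null, logical(1))

  emit <- function(name, df) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  if ("smiles" %in% config$outputs && any(ok)) {
    emit("smiles.csv", data.frame(
      sequence = seqs[ok],
      cyclic = cyc[ok],
      atom_mapped_smiles = vapply(peptides[ok], `[[`, "", "smiles"),
      canonical_smiles = vapply(peptides[ok],
                                function(p) canonical_smiles(p$smiles), ""),
      residue_of_atom = vapply(peptides[ok], function(p)
        paste(p$residue_of_atom - 1L, collapse = ";"), "")
    ))
  }

  if ("graph" %in% config$outputs && any(ok)) {
    idx <- data.frame(sequence = character(), file = character())
    for (i in which(ok)) {
      g <- build_graph(peptides[[i]], lib,
                       include_chirality = config$include_chirality,
                       directed_duplication = config$directed_duplication)
      f <- file.path(config$out_dir, sprintf("graph_%04d.json", i))
      export_graph(g, f)
      files <- c(files, f)
      idx <- rbind(idx, data.frame(sequence = seqs[i], file = basename(f)))
    }
    emit("graph_index.csv", idx)
  }

  if ("morgan" %in% config$outputs && any(ok)) {
    emit("morgan.csv", data.frame(
      sequence = seqs[ok],
      n_bits = config$morgan_bits,
      radius = config$morgan_radius,
      fingerprint = vapply(peptides[ok], function(p)
        paste(morgan_fingerprint(p, config$morgan_bits,
                                 config$morgan_radius), collapse = ""), "")
    ))
  }

  if ("maccs" %in% config$outputs && any(ok)) {
    emit("maccs.csv", data.frame(
      sequence = seqs[ok],
      n_bits = 166L,
      fingerprint = vapply(peptides[ok], function(p)
        paste(maccs_keys(p), collapse = ""), "")
    ))
  }

  if ("onehot" %in% config$outputs && any(ok)) {
    alphabet <- library_tokens(lib)
    max_len <- config$onehot_max_len
    if (is.null(max_len))
      max_len <- max(vapply(peptides[ok], function(p)
        length(p$tokens), integer(1)))
    emit("onehot.csv", data.frame(
      sequence = seqs[ok],
      max_len = max_len,
      alphabet_size = length(alphabet),
      encoding = vapply(peptides[ok], function(p)
        paste(onehot_encode(p$tokens, alphabet, max_len, flatten = TRUE),
              collapse = ""), "")
    ))
  }

  failures <- data.frame(row = which(!ok), sequence = seqs[!ok],
                         error = errors[!ok])
  report <- structure(
    list(n_ok = sum(ok), n_failed = sum(!ok), failures = failures,
         files = unique(files)),
    class = "run_report"
  )
  emit("report.csv", data.frame(row = seq_along(seqs), sequence = seqs,
                                ok = ok, error = ifelse(ok, "", errors)))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$n_ok, " ok, ", x$n_failed, " failed\n", sep = "")
  if (x$n_failed > 0) {
    for (i in seq_len(nrow(x$failures)))
      cat("  row ", x$failures$row[i], " (", x$failures$sequence[i], "): ",
          x$failures$error[i], "\n", sep = "")
  }
  invisible(x)
}
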