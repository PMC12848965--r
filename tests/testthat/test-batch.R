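# batch front end

write_batch_input <- function(seqs, cyclic = NULL) {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(sequence = seqs)
  if (!is.null(cyclic)) df$cyclic <- cyclic
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("a clean batch converts every row", {
  inp <- write_batch_input(c("AGLW", "a{Aib}K", "GG"))
  out <- tempfile()
  rep <- run_batch(run_config(inp, out, outputs = "smiles"))
  expect_equal(rep$n_ok, 3L)
  expect_equal(rep$n_failed, 0L)
  tab <- utils::read.csv(file.path(out, "smiles.csv"))
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("atom_mapped_smiles", "canonical_smiles",
                    "residue_of_atom") %in% names(tab)))
})

test_that("a bad row is reported, not fatal, and names the token", {
  inp <- write_batch_input(c("AG", "A{bad}G"))
  out <- tempfile()
  rep <- run_batch(run_config(inp, out, outputs = "smiles"))
  expect_equal(rep$n_ok, 1L)
  expect_equal(rep$n_failed, 1L)
  expect_match(rep$failures$error[1], "\\{bad\\}")
  expect_equal(nrow(utils::read.csv(file.path(out, "smiles.csv"))), 1L)
  report <- utils::read.csv(file.path(out, "report.csv"))
  expect_equal(nrow(report), 2L)
})

test_that("graph output writes one container per sequence plus an index", {
  inp <- write_batch_input(c("AG", "GG"), cyclic = c(FALSE, TRUE))
  out <- tempfile()
  rep <- run_batch(run_config(inp, out, outputs = "graph",
                              include_chirality = TRUE))
  expect_equal(rep$n_failed, 0L)
  idx <- utils::read.csv(file.path(out, "graph_index.csv"))
  expect_equal(nrow(idx), 2L)
  for (f in idx$file) {
    g <- import_graph(file.path(out, f))
    expect_equal(ncol(g$node_features), 27L)
  }
})

test_that("re-running an identical configuration is byte-identical", {
  inp <- write_batch_input(c("AKF", "GG"))
  out1 <- tempfile(); out2 <- tempfile()
  run_batch(run_config(inp, out1, outputs = c("smiles", "morgan", "maccs",
                                              "onehot")))
  run_batch(run_config(inp, out2, outputs = c("smiles", "morgan", "maccs",
                                              "onehot")))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = paste("determinism of", f))
  }
})

test_that("run_config validates its output selection", {
  expect_error(run_config("x.csv", "out", outputs = character(0)),
               "at least one")
  expect_error(run_config("x.csv", "out", outputs = "bogus"), "arg")
})

test_that("the command-line front end converts a batch end to end", {
  cli <- system.file("exec", "chuckles", package = "chuckles")
  if (!nzchar(cli)) cli <- system.file("../exec/chuckles", package = "chuckles")
  stopifnot(nzchar(cli))
  inp <- write_batch_input(c("AG", "GG"))
  out <- tempfile()
  res <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"),
    c(cli, "convert", "--input", inp, "--out-dir", out),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0L)
  expect_true(file.exists(file.path(out, "smiles.csv")))
  expect_equal(nrow(utils::read.csv(file.path(out, "smiles.csv"))), 2L)
})
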