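# residue library loading, validation, flags

test_that("default library has 157 validated entries across all classes", {
  lib <- load_default_library(validate = TRUE)  # full per-entry validation
  expect_s3_class(lib, "residue_library")
  expect_equal(length(lib), 157L)
  expect_setequal(unique(lib$entries$class),
                  c("canonical", "d_isomer", "ncaa", "peptoid",
                    "n_cap", "c_cap", "polymer"))
  expect_equal(sum(lib$entries$class == "canonical"), 20L)
  expect_equal(sum(lib$entries$class == "d_isomer"), 19L)
  expect_equal(sum(lib$entries$class == "peptoid"), 18L)

  a <- lib[["A"]]
  expect_equal(a$chirality, "L")
  expect_equal(a$class, "canonical")
})

test_that("lowercase entries are enantiomers of their uppercase partners", {
  lib <- default_lib()
  for (t in setdiff(CANONICAL_AA, "G")) {
    ls <- lib[[t]]$smiles
    ds <- lib[[tolower(t)]]$smiles
    expect_identical(canonical_smiles(invert_stereo(ls)),
                     canonical_smiles(ds),
                     label = paste("enantiomer pair", t))
    expect_identical(formula_string(mol_formula(parse_smiles(ls))),
                     formula_string(mol_formula(parse_smiles(ds))))
  }
})

test_that("every entry matches its stored reference canonical form", {
  lib <- default_lib()
  expect_identical(canonical_smiles(lib$entries$smiles),
                   lib$entries$reference_canonical)
})

test_that("custom tables load with inferred chirality and preserved order", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Token,SMILES (CHUCKLES)",
               "G,\"[NH2:1]C[C:2](=O)O\"",
               "A,\"[NH2:1][C@@H](C)[C:2](=O)O\""), f)
  lib <- load_residue_library(f)
  expect_equal(length(lib), 2L)
  expect_equal(library_tokens(lib), c("G", "A"))
  expect_equal(lib[["A"]]$chirality, "L")
  expect_equal(lib[["G"]]$chirality, "achiral")
})

test_that("bad custom tables fail with row-level diagnostics", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Token,SMILES (CHUCKLES)",
               "A,\"[NH2:1][C@@H](C)[C:2](=O)O\"",
               "A,\"[NH2:1][C@@H](C)[C:2](=O)O\""), f)
  expect_error(load_residue_library(f), "duplicate token")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("Token,SMILES (CHUCKLES)",
               "A,\"[NH2:1][C@@H](C)C(=O)O\""), f2)  # no map 2
  expect_error(load_residue_library(f2), "row 1.*map|map.*row 1")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("Token,Name", "A,alanine"), f3)
  expect_error(load_residue_library(f3), "SMILES")
})

test_that("validate_entry reports pass/fail instead of raising", {
  ok <- validate_entry(residue_entry("A", "[NH2:1][C@@H](C)[C:2](=O)O",
                                     "L", "canonical", alpha_cip = "S"))
  expect_true(attr(ok, "ok"))

  gly <- validate_entry(residue_entry("G", "[NH2:1]C[C:2](=O)O",
                                      "achiral", "canonical",
                                      alpha_cip = "none"))
  expect_true(attr(gly, "ok"))

  nomap <- validate_entry(residue_entry("A", "N[C@@H](C)C(=O)O",
                                        "L", "canonical"))
  expect_false(attr(nomap, "ok"))
  expect_false(nomap$pass[nomap$check == "map1_nitrogen_first"])

  badcip <- validate_entry(residue_entry("A", "[NH2:1][C@@H](C)[C:2](=O)O",
                                         "L", "canonical", alpha_cip = "R"))
  expect_false(attr(badcip, "ok"))

  badtok <- validate_entry(residue_entry("Abc", "[NH2:1]C[C:2](=O)O"))
  expect_false(badtok$pass[badtok$check == "token_grammar"])
})

test_that("cap entries carry exactly one terminal map", {
  lib <- default_lib()
  ac <- parse_smiles(lib[["{ac}"]]$smiles)
  expect_equal(sum(ac$atoms$map == 2L), 1L)
  expect_equal(sum(ac$atoms$map == 1L), 0L)
  am <- parse_smiles(lib[["{am}"]]$smiles)
  expect_equal(sum(am$atoms$map == 1L), 1L)
  expect_equal(sum(am$atoms$map == 2L), 0L)
})

test_that("write -> load round trip reproduces the library entry-by-entry", {
  lib <- default_lib()
  f <- tempfile(fileext = ".csv")
  write_residue_library(lib, f)
  lib2 <- load_residue_library(f, validate = FALSE)
  expect_equal(lib2$entries$token, lib$entries$token)
  expect_equal(lib2$entries$smiles, lib$entries$smiles)
  expect_equal(lib2$entries$chirality, lib$entries$chirality)
  expect_equal(lib2$entries$class, lib$entries$class)
  expect_equal(lib2$entries$alpha_cip, lib$entries$alpha_cip)
})

test_that("residue flags follow the L/D/achiral convention", {
  lib <- default_lib()
  expect_equal(residue_flag(lib[["F"]]), c(1L, 0L))
  expect_equal(residue_flag(lib[["f"]]), c(0L, 1L))
  expect_equal(residue_flag(lib[["{NPhe}"]]), c(0L, 0L))
  expect_equal(residue_flag(lib[["G"]]), c(0L, 0L))
  expect_equal(residue_flag(lib[["{PEG2}"]]), c(0L, 0L))
})

test_that("XLSX-style loading is exercised when readxl is present", {
  skip_if_not_installed("readxl")
  # readxl cannot write; verify the CSV/XLSX dispatch picks the right reader
  expect_error(load_residue_library(tempfile(fileext = ".xlsx")), "not found")
  f <- tempfile(fileext = ".tsv")
  writeLines("x", f)
  expect_error(load_residue_library(f), "unsupported")
})
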