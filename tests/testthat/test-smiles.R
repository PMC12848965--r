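# SMILES reader/writer core

test_that("parser recovers atoms, bonds, maps and implicit hydrogens", {
  m <- parse_smiles("[NH2:1][C@@H](C)[C:2](=O)O")
  expect_equal(nrow(m$atoms), 6L)
  expect_equal(nrow(m$bonds), 5L)
  expect_equal(m$atoms$element, c("N", "C", "C", "C", "O", "O"))
  expect_equal(m$atoms$map, c(1L, 0L, 0L, 2L, 0L, 0L))
  # bracket H counts kept; organic-subset H filled from default valence
  expect_equal(m$atoms$hcount, c(2L, 1L, 3L, 0L, 0L, 1L))
  expect_equal(unname(mol_formula(m)), c(3L, 7L, 1L, 2L))
  expect_equal(names(mol_formula(m)), c("C", "H", "N", "O"))

  arom <- parse_smiles("Cc1ccc(O)cc1")
  expect_equal(sum(arom$atoms$aromatic), 6L)
  expect_equal(sum(arom$bonds$aromatic), 6L)
  expect_equal(formula_string(mol_formula(arom)), "C7H8O")

  charged <- parse_smiles("C[N+](C)(C)C")
  expect_equal(charged$atoms$charge[2], 1L)
  expect_equal(charged$atoms$hcount[2], 0L)
})

test_that("parser rejects malformed and unsupported input", {
  expect_error(parse_smiles("C(C"), "unclosed branch")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CC)C"), "unbalanced")
  expect_error(parse_smiles("C.C"), "disconnected")
  expect_error(parse_smiles("F/C=C/F"), "directional")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_smiles("[Xx]"), "unknown element")
  expect_error(parse_smiles(""), "empty")
})

test_that("ring closures support %NN labels and bond symbols", {
  a <- parse_smiles("C1CCCCC1")
  b <- parse_smiles("C%99CCCCC%99")
  expect_identical(canonical_smiles(write_smiles(a)),
                   canonical_smiles(write_smiles(b)))
  expect_equal(nrow(a$bonds), 6L)
})

test_that("writer round-trips every default library entry", {
  lib <- default_lib()
  for (i in seq_len(nrow(lib$entries))) {
    s <- lib$entries$smiles[i]
    m <- parse_smiles(s)
    w <- write_smiles(m)
    expect_identical(canonical_smiles(w), canonical_smiles(s),
                     label = paste("round trip of", lib$entries$token[i]))
    # maps survive the rewrite
    m2 <- parse_smiles(w)
    expect_identical(sort(m2$atoms$map[m2$atoms$map > 0]),
                     sort(m$atoms$map[m$atoms$map > 0]))
  }
})

test_that("stereo inversion is an enantiomer involution", {
  s <- "N[C@@H](CS)C(=O)O"
  expect_identical(invert_stereo(invert_stereo(s)), s)
  expect_false(identical(canonical_smiles(s),
                         canonical_smiles(invert_stereo(s))))
  # inversion leaves the constitution (formula, canonical skeleton) intact
  expect_identical(formula_string(mol_formula(parse_smiles(s))),
                   formula_string(mol_formula(parse_smiles(invert_stereo(s)))))
})

test_that("formula arithmetic matches hand-computed sums", {
  gly <- mol_formula(parse_smiles("NCC(=O)O"))
  water <- c(H = 2L, O = 1L)
  gg <- formula_sum(gly, gly, water, mult = c(1, 1, -1))
  expect_identical(formula_string(gg), "C4H8N2O3")
  expect_error(formula_sum(c(C = 1L), c(C = 2L), mult = c(1, -1)), "negative")
})
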