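# CHUCKLES assembly

test_that("glycylglycine assembles to the hand-written dipeptide", {
  lib <- default_lib()
  gg <- assemble_peptide("GG", lib)
  expect_equal(gg$smiles, "[NH2:1]C[C:2](=O)[NH:1]C[C:2](=O)O")
  expect_identical(canonical_smiles(gg$smiles),
                   canonical_smiles("NCC(=O)NCC(=O)O"))
  expect_equal(formula_string(mol_formula(gg$mol)), "C4H8N2O3")
  expect_equal(nrow(gg$peptide_bonds), 1L)
})

test_that("a single residue assembles to the library entry itself", {
  lib <- default_lib()
  a <- assemble_peptide("A", lib)
  expect_identical(a$smiles, lib[["A"]]$smiles)
  expect_equal(nrow(a$peptide_bonds), 0L)
  expect_equal(a$residue_of_atom, rep(1L, mol_natoms(a$mol)))
})

test_that("cyclization closes the head-to-tail ring", {
  lib <- default_lib()
  cgg <- assemble_peptide("GG", lib, cyclic = TRUE)
  expect_identical(canonical_smiles(cgg$smiles),
                   canonical_smiles("O=C1CNC(=O)CN1"))  # 2,5-diketopiperazine
  expect_equal(nrow(cgg$peptide_bonds), 2L)

  cggg <- assemble_peptide("GGG", lib, cyclic = TRUE)
  expect_equal(formula_string(mol_formula(cggg$mol)), "C6H9N3O3")
  expect_equal(nrow(cggg$peptide_bonds), 3L)

  expect_error(assemble_peptide("A", lib, cyclic = TRUE), "at least 2")
})

test_that("residue mapping splits atoms at the amide junctions", {
  lib <- default_lib()
  gg <- assemble_peptide("GG", lib)
  expect_equal(sum(gg$residue_of_atom == 1L), 4L)  # N,C,C,O
  expect_equal(sum(gg$residue_of_atom == 2L), 5L)  # N,C,C,O,O
  cgg <- assemble_peptide("GG", lib, cyclic = TRUE)
  expect_equal(as.integer(table(cgg$residue_of_atom)), c(4L, 4L))
  expect_identical(residue_mapping(gg), gg$residue_of_atom)
})

test_that("caps concatenate like residues and count in the mapping", {
  lib <- default_lib()
  p <- assemble_peptide("{ac}AG{am}", lib)
  expect_equal(length(unique(p$residue_of_atom)), 4L)
  expect_equal(nrow(p$peptide_bonds), 3L)  # k-1 with caps as residues
  expect_identical(mol_formula(p$mol),
                   expected_formula(p$tokens, lib, nrow(p$peptide_bonds)))
  # N-acetyl, C-amide termini present
  expect_match(canonical_smiles(p$smiles), "N")
})

test_that("formula conservation holds across random library sequences", {
  lib <- default_lib()
  set.seed(99)
  for (i in 1:40) {
    cyc <- i %% 2 == 0
    s <- random_library_sequence(lib, cyclic = cyc)
    p <- assemble_peptide(s, lib, cyclic = cyc)
    k <- length(p$tokens)
    expect_equal(nrow(p$peptide_bonds), if (cyc) k else k - 1L,
                 label = paste("bond count of", s))
    expect_identical(mol_formula(p$mol),
                     expected_formula(p$tokens, lib, nrow(p$peptide_bonds)),
                     label = paste("formula of", s))
    expect_equal(sort(unique(p$residue_of_atom)), seq_len(k),
                 label = paste("mapping of", s))
  }
})

test_that("assembly agrees with the independent sequence converter", {
  lib <- default_lib()
  set.seed(11)
  seqs <- vapply(1:25, function(i)
    paste(sample(CANONICAL_AA, sample(1:10, 1), replace = TRUE),
          collapse = ""), character(1))
  ref <- rdkit_seq_smiles(seqs)
  for (i in seq_along(seqs)) {
    mine <- canonical_smiles(assemble_peptide(seqs[i], lib)$smiles)
    expect_identical(mine, canonical_smiles(ref[i]),
                     label = paste("oracle equivalence for", seqs[i]))
  }
})

test_that("lowercasing a sequence yields the mirror-image peptide", {
  lib <- default_lib()
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(setdiff(CANONICAL_AA, "G"), sample(2:8, 1),
                      replace = TRUE), collapse = "")
    l <- assemble_peptide(s, lib)
    d <- assemble_peptide(tolower(s), lib)
    expect_identical(canonical_smiles(invert_stereo(l$smiles)),
                     canonical_smiles(d$smiles),
                     label = paste("enantiomer assembly of", s))
  }
})

test_that("the junction rule is local (assembly is associative)", {
  lib <- default_lib()
  whole <- assemble_peptide("AKF", lib)
  # join the assembled "AK" to "F" with the same junction surgery
  ab <- assemble_peptide("AK", lib)
  left <- sub("O$", "", ab$smiles)           # drop the C-terminal hydroxyl
  right <- chuckles:::.decrement_bracket_h(lib[["F"]]$smiles, "F")
  expect_identical(canonical_smiles(paste0(left, right)),
                   canonical_smiles(whole$smiles))
})

test_that("assembly failures carry diagnostics", {
  lib <- default_lib()
  expect_error(assemble_peptide("A{bad}G", lib), "not in the residue library")
  # a residue with no removable N-H cannot accept a bond
  f <- tempfile(fileext = ".csv")
  writeLines(c("Token,SMILES (CHUCKLES),Class",
               "G,\"[NH2:1]C[C:2](=O)O\",canonical",
               "{X},\"[N:1](C)(C)C[C:2](=O)O\",ncaa"), f)
  lib2 <- load_residue_library(f, validate = FALSE)
  expect_error(assemble_peptide("G{X}", lib2), "cannot accept")
})
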