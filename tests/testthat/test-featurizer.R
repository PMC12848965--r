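# graph featurization

test_that("feature matrices have the documented dimensions", {
  lib <- default_lib()
  p <- assemble_peptide("AG", lib)
  g <- build_graph(p, lib)
  expect_equal(ncol(g$node_features), 24L)
  expect_equal(ncol(g$edge_features), 16L)
  expect_equal(nrow(g$node_features), mol_natoms(p$mol))
  expect_equal(nrow(g$adjacency), 2L)
  expect_equal(ncol(g$adjacency), 2L * mol_nbonds(p$mol))

  gc <- build_graph(p, lib, include_chirality = TRUE)
  expect_equal(ncol(gc$node_features), 27L)

  g1 <- build_graph(p, lib, directed_duplication = FALSE)
  expect_equal(ncol(g1$adjacency), mol_nbonds(p$mol))
  expect_equal(nrow(g1$edge_features), mol_nbonds(p$mol))
})

test_that("one-hot blocks are proper one-hots and adjacency is symmetric", {
  lib <- default_lib()
  set.seed(31)
  for (i in 1:8) {
    cyc <- i %% 3 == 0
    s <- random_library_sequence(lib, cyclic = cyc)
    p <- assemble_peptide(s, lib, cyclic = cyc)
    g <- build_graph(p, lib, include_chirality = TRUE)
    n <- nrow(g$node_features)
    expect_equal(unname(rowSums(g$node_features[, 1:10, drop = FALSE])),
                 rep(1, n), label = paste("element block", s))
    expect_equal(unname(rowSums(g$node_features[, 11:15, drop = FALSE])),
                 rep(1, n), label = paste("degree block", s))
    expect_equal(unname(rowSums(g$node_features[, 16:19, drop = FALSE])),
                 rep(1, n), label = paste("H block", s))
    expect_equal(unname(rowSums(g$node_features[, 25:27, drop = FALSE])),
                 rep(1, n), label = paste("chirality block", s))
    e <- nrow(g$edge_features)
    expect_equal(unname(rowSums(g$edge_features[, 1:4, drop = FALSE])),
                 rep(1, e), label = paste("bond type block", s))
    expect_equal(unname(rowSums(g$edge_features[, 7:10, drop = FALSE])),
                 rep(1, e), label = paste("stereo block", s))
    # directed edge set is symmetric
    fwd <- paste(g$adjacency[1, ], g$adjacency[2, ])
    rev <- paste(g$adjacency[2, ], g$adjacency[1, ])
    expect_setequal(fwd, rev)
    # connected single molecule
    gr <- igraph::graph_from_edgelist(t(g$adjacency), directed = FALSE)
    expect_equal(igraph::components(gr)$no, 1L)
  }
})

test_that("glycine atoms are all chirality-not-defined", {
  lib <- default_lib()
  g <- build_graph(assemble_peptide("G", lib), lib, include_chirality = TRUE)
  expect_true(all(g$node_features[, "cip_not_defined"] == 1))
  expect_true(all(g$node_features[, c("cip_s", "cip_r")] == 0))
})

test_that("L and D peptides differ only in the swapped S/R columns", {
  lib <- default_lib()
  set.seed(17)
  for (i in 1:6) {
    s <- paste(sample(setdiff(CANONICAL_AA, "G"), sample(2:6, 1),
                      replace = TRUE), collapse = "")
    gl <- build_graph(assemble_peptide(s, lib), lib, include_chirality = TRUE)
    gd <- build_graph(assemble_peptide(tolower(s), lib), lib,
                      include_chirality = TRUE)
    base <- seq_len(24L)
    expect_identical(gl$node_features[, base], gd$node_features[, base],
                     label = paste("achiral features of", s))
    expect_identical(unname(gl$node_features[, "cip_s"]),
                     unname(gd$node_features[, "cip_r"]),
                     label = paste("S/R swap of", s))
    expect_identical(unname(gl$node_features[, "cip_r"]),
                     unname(gd$node_features[, "cip_s"]))
    expect_identical(gl$edge_features, gd$edge_features)
    expect_identical(gl$residue_flags[, 1], gd$residue_flags[, 2])
  }
})

test_that("atom feature vectors describe the chemistry", {
  lib <- default_lib()
  p <- assemble_peptide("AF", lib)
  M <- g <- build_graph(p, lib)$node_features
  at <- p$mol$atoms
  # alpha carbon of Ala: carbon, sp3, non-aromatic, non-ring
  ca <- 2L
  expect_equal(unname(M[ca, "element_C"]), 1)
  expect_equal(unname(M[ca, "hyb_sp3"]), 1)
  expect_equal(unname(M[ca, c("is_aromatic", "in_ring")]), c(0, 0))
  # backbone amide N: nitrogen with two heavy neighbors
  amide_n <- which(at$map == 1L)[2]
  expect_equal(unname(M[amide_n, "element_N"]), 1)
  expect_equal(unname(M[amide_n, "degree_2"]), 1)
  # Phe ring carbons: aromatic, in ring
  ring <- which(at$aromatic)
  expect_true(all(M[ring, "is_aromatic"] == 1))
  expect_true(all(M[ring, "in_ring"] == 1))
  expect_true(all(M[ring, "hyb_sp2"] == 1))
})

test_that("bond feature vectors mark amide, aromatic and rotatable bonds", {
  lib <- default_lib()
  p <- assemble_peptide("AF", lib)
  g <- build_graph(p, lib, directed_duplication = FALSE)
  b <- p$mol$bonds
  E <- g$edge_features
  # the peptide bond: single, conjugated, flagged, inter-residue, not rotatable
  pb <- which(E[, "is_peptide_bond"] == 1)
  expect_equal(length(pb), 1L)
  expect_equal(unname(E[pb, "bond_single"]), 1)
  expect_equal(unname(E[pb, "is_conjugated"]), 1)
  expect_equal(unname(E[pb, "is_intra_residue"]), 0)
  expect_equal(unname(E[pb, "is_rotatable"]), 0)
  # aromatic ring bonds: aromatic type, ring, size 6
  ar <- which(b$aromatic)
  expect_true(all(E[ar, "bond_aromatic"] == 1))
  expect_true(all(E[ar, "in_ring"] == 1))
  expect_true(all(E[ar, "ring_size_6"] == 1))
  # Ala Calpha-Cbeta: single, non-ring, unflagged
  cb <- which(b$a1 == 2L & b$a2 == 3L)
  expect_equal(unname(E[cb, "bond_single"]), 1)
  expect_equal(unname(E[cb, c("in_ring", "is_peptide_bond")]), c(0, 0))
  expect_equal(unname(E[cb, "is_conjugated"]), 0)
})

test_that("proline's five-membered ring is sized correctly", {
  lib <- default_lib()
  p <- assemble_peptide("PG", lib)
  g <- build_graph(p, lib, directed_duplication = FALSE)
  ring_rows <- which(g$edge_features[, "in_ring"] == 1)
  expect_equal(length(ring_rows), 5L)
  expect_true(all(g$edge_features[ring_rows, "ring_size_5"] == 1))
})

test_that("out-of-vocabulary elements fail with advice", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Token,SMILES (CHUCKLES),Class",
               "{IPhe},\"[NH2:1][C@@H](Cc1ccc(I)cc1)[C:2](=O)O\",ncaa"), f)
  lib2 <- load_residue_library(f, validate = FALSE)
  p <- assemble_peptide("{IPhe}", lib2)
  expect_error(build_graph(p, lib2), "I.*custom|custom.*I")
  g <- build_graph(p, lib2, extra_elements = "I")
  expect_equal(sum(g$node_features[, "element_other"]), 1)
})

test_that("graph containers round-trip losslessly with named metadata", {
  lib <- default_lib()
  p <- assemble_peptide("{ac}aKw", lib)
  g <- build_graph(p, lib, include_chirality = TRUE)
  f <- tempfile(fileext = ".json")
  export_graph(g, f)
  g2 <- import_graph(f)
  expect_identical(unname(g$node_features), unname(g2$node_features))
  expect_identical(unname(g$edge_features), unname(g2$edge_features))
  expect_identical(g$adjacency, g2$adjacency)
  expect_identical(g$residue_of_atom, g2$residue_of_atom)
  expect_identical(unname(g$residue_flags), unname(g2$residue_flags))
  meta <- jsonlite::read_json(f, simplifyVector = TRUE)$metadata
  expect_equal(length(meta$atom_feature_names), 27L)
  expect_equal(meta$atom_feature_names, atom_feature_names(TRUE))
  expect_equal(meta$bond_feature_names, bond_feature_names())
  expect_equal(meta$index_base, 0L)
  # serialized indices are 0-based
  expect_equal(min(jsonlite::read_json(f, simplifyVector = TRUE)$residue_of_atom), 0L)
})
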