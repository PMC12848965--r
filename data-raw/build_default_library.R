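# Builds inst/extdata/residue_library.csv (the 157-entry default library).
# Run from the package root:  Rscript data-raw/build_default_library.R
# Cross-checks every entry against OpenBabel canonicalization and, when a
# python interpreter with RDKit is on PATH, against RDKit CIP labels and
# RDKit's one-letter sequence builder before writing the file.

devtools::load_all(".", quiet = TRUE)

AA1 <- c("A","R","N","D","C","Q","E","G","H","I","K","L","M","F","P",
         "S","T","W","Y","V")
AA3 <- c(A="Ala", R="Arg", N="Asn", D="Asp", C="Cys", Q="Gln", E="Glu",
         G="Gly", H="His", I="Ile", K="Lys", L="Leu", M="Met", F="Phe",
         P="Pro", S="Ser", T="Thr", W="Trp", Y="Tyr", V="Val")
AANAME <- c(A="L-alanine", R="L-arginine", N="L-asparagine", D="L-aspartic acid",
            C="L-cysteine", Q="L-glutamine", E="L-glutamic acid", G="glycine",
            H="L-histidine", I="L-isoleucine", K="L-lysine", L="L-leucine",
            M="L-methionine", F="L-phenylalanine", P="L-proline", S="L-serine",
            T="L-threonine", W="L-tryptophan", Y="L-tyrosine", V="L-valine")
CAS <- c(A="56-41-7", R="74-79-3", N="70-47-3", D="56-84-8", C="52-90-4",
         Q="56-85-9", E="56-86-0", G="56-40-6", H="71-00-1", I="73-32-5",
         K="56-87-1", L="61-90-5", M="63-68-3", F="63-91-2", P="147-85-3",
         S="56-45-1", T="72-19-5", W="73-22-3", Y="60-18-4", V="72-18-4")

# side chains of the chiral canonical residues, as written after the alpha
# carbon ("[NH2:1][C@@H](<side>)[C:2](=O)O")
SIDE <- c(A="C", R="CCCNC(=N)N", N="CC(N)=O", D="CC(=O)O", C="CS",
          Q="CCC(N)=O", E="CCC(=O)O", H="Cc1c[nH]cn1", I="[C@@H](C)CC",
          K="CCCCN", L="CC(C)C", M="CCSC", F="Cc1ccccc1", S="CO",
          T="[C@H](O)C", W="Cc1c[nH]c2ccccc12", Y="Cc1ccc(O)cc1",
          V="C(C)C")

l_chuckles <- function(side) paste0("[NH2:1][C@@H](", side, ")[C:2](=O)O")

rows <- list()
add <- function(token, name, smiles, chirality, class, cas = "", acip = "") {
  rows[[length(rows) + 1L]] <<- data.frame(
    Token = token, Name = name, `SMILES (CHUCKLES)` = smiles,
    Chirality = chirality, Class = class, CAS = cas, AlphaCIP = acip,
    check.names = FALSE)
}

## 20 canonical L residues --------------------------------------------------
for (a in AA1) {
  smi <- if (a == "G") "[NH2:1]C[C:2](=O)O"
  else if (a == "P") "[NH:1]1CCC[C@H]1[C:2](=O)O"
  else l_chuckles(SIDE[[a]])
  acip <- if (a == "G") "none" else if (a == "C") "R" else "S"
  add(a, AANAME[[a]], smi, if (a == "G") "achiral" else "L", "canonical",
      CAS[[a]], acip)
}

## 19 D isomers (no D-glycine) ----------------------------------------------
for (a in setdiff(AA1, "G")) {
  lsmi <- if (a == "P") "[NH:1]1CCC[C@H]1[C:2](=O)O" else l_chuckles(SIDE[[a]])
  add(tolower(a), sub("^L-", "D-", AANAME[[a]]), invert_stereo(lsmi),
      "D", "d_isomer", "", if (a == "C") "S" else "R")
}

## 18 peptoid analogs (no Gly/Pro analog) -----------------------------------
for (a in setdiff(AA1, c("G", "P"))) {
  add(paste0("{N", AA3[[a]], "}"),
      paste0("peptoid analog of ", sub("^L-", "", AANAME[[a]])),
      paste0("[NH:1](", SIDE[[a]], ")C[C:2](=O)O"),
      "achiral", "peptoid", "", "none")
}

## 18 N-methyl variants -----------------------------------------------------
for (a in setdiff(AA1, c("G", "P"))) {
  add(paste0("{Me", a, "}"), paste0("N-methyl-", AANAME[[a]]),
      paste0("[NH:1](C)[C@@H](", SIDE[[a]], ")[C:2](=O)O"),
      "L", "ncaa", "", if (a == "C") "R" else "S")
}

## 6 end caps ---------------------------------------------------------------
add("{ac}", "acetyl (N-cap)", "C[C:2](=O)O", "achiral", "n_cap")
add("{fo}", "formyl (N-cap)", "[CH:2](=O)O", "achiral", "n_cap")
add("{bz}", "benzoyl (N-cap)", "c1ccccc1[C:2](=O)O", "achiral", "n_cap")
add("{am}", "amide (C-cap)", "[NH3:1]", "achiral", "c_cap")
add("{nme}", "N-methylamide (C-cap)", "[NH2:1]C", "achiral", "c_cap")
add("{dma}", "N,N-dimethylamide (C-cap)", "[NH:1](C)C", "achiral", "c_cap")

## 4 PEG polymer units ------------------------------------------------------
for (n in 1:4) {
  add(paste0("{PEG", n, "}"),
      paste0("amino-PEG", n, "-acid polymer unit"),
      paste0("[NH2:1]", strrep("CCO", n), "C[C:2](=O)O"),
      "achiral", "polymer", "", "none")
}

## 30 L/D NCAA pairs ---------------------------------------------------------
NCAA <- list(
  # token-stem, name, side chain (attached at the alpha carbon), L alpha CIP
  list("Orn", "ornithine", "CCCN", "S"),
  list("Dab", "2,4-diaminobutyric acid", "CCN", "S"),
  list("Dap", "2,3-diaminopropionic acid", "CN", "S"),
  list("Cit", "citrulline", "CCCNC(N)=O", "S"),
  list("Nle", "norleucine", "CCCC", "S"),
  list("Nva", "norvaline", "CCC", "S"),
  list("Abu", "2-aminobutyric acid", "CC", "S"),
  list("Hse", "homoserine", "CCO", "S"),
  list("Hcy", "homocysteine", "CCS", "S"),
  list("Phg", "phenylglycine", "c1ccccc1", "S"),
  list("Hph", "homophenylalanine", "CCc1ccccc1", "S"),
  list("Cha", "cyclohexylalanine", "CC1CCCCC1", "S"),
  list("1Nal", "1-naphthylalanine", "Cc1cccc2ccccc12", "S"),
  list("2Nal", "2-naphthylalanine", "Cc1ccc2ccccc2c1", "S"),
  list("Phe4F", "4-fluorophenylalanine", "Cc1ccc(F)cc1", "S"),
  list("Phe4Cl", "4-chlorophenylalanine", "Cc1ccc(Cl)cc1", "S"),
  list("Phe4Br", "4-bromophenylalanine", "Cc1ccc(Br)cc1", "S"),
  list("Phe4Me", "4-methylphenylalanine", "Cc1ccc(C)cc1", "S"),
  list("Phe4NO2", "4-nitrophenylalanine", "Cc1ccc([N+](=O)[O-])cc1", "S"),
  list("2Pal", "2-pyridylalanine", "Cc1ccccn1", "S"),
  list("3Pal", "3-pyridylalanine", "Cc1cccnc1", "S"),
  list("4Pal", "4-pyridylalanine", "Cc1ccncc1", "S"),
  list("Thi", "2-thienylalanine", "Cc1cccs1", "S"),
  list("Fua", "2-furylalanine", "Cc1ccco1", "S"),
  list("Sec", "selenocysteine", "C[SeH]", "R"),
  list("Mox", "methionine sulfoxide", "CCS(C)=O", "S"),
  list("Dopa", "3,4-dihydroxyphenylalanine", "Cc1ccc(O)c(O)c1", "S"),
  list("Tle", "tert-leucine", "C(C)(C)C", "S"),
  list("Aad", "2-aminoadipic acid", "CCCC(=O)O", "S"),
  list("Agl", "allylglycine", "CC=C", "S")
)
stopifnot(length(NCAA) == 30L)
for (x in NCAA) {
  lsmi <- l_chuckles(x[[3]])
  add(paste0("{", x[[1]], "}"), paste0("L-", x[[2]]), lsmi, "L", "ncaa",
      "", x[[4]])
  add(paste0("{d", x[[1]], "}"), paste0("D-", x[[2]]), invert_stereo(lsmi),
      "D", "ncaa", "", if (x[[4]] == "S") "R" else "S")
}

## 12 achiral or single-stereoform extras ------------------------------------
add("{Aib}", "2-aminoisobutyric acid", "[NH2:1]C(C)(C)[C:2](=O)O",
    "achiral", "ncaa", "", "none")
add("{bAla}", "beta-alanine", "[NH2:1]CC[C:2](=O)O", "achiral", "ncaa",
    "", "none")
add("{GABA}", "4-aminobutyric acid", "[NH2:1]CCC[C:2](=O)O", "achiral",
    "ncaa", "", "none")
add("{Ava}", "5-aminovaleric acid", "[NH2:1]CCCC[C:2](=O)O", "achiral",
    "ncaa", "", "none")
add("{Ahx}", "6-aminohexanoic acid", "[NH2:1]CCCCC[C:2](=O)O", "achiral",
    "ncaa", "", "none")
add("{Ac3c}", "1-aminocyclopropanecarboxylic acid",
    "[NH2:1]C1(CC1)[C:2](=O)O", "achiral", "ncaa", "", "none")
add("{Ac5c}", "1-aminocyclopentanecarboxylic acid",
    "[NH2:1]C1(CCCC1)[C:2](=O)O", "achiral", "ncaa", "", "none")
add("{Ac6c}", "1-aminocyclohexanecarboxylic acid",
    "[NH2:1]C1(CCCCC1)[C:2](=O)O", "achiral", "ncaa", "", "none")
add("{Deg}", "diethylglycine", "[NH2:1]C(CC)(CC)[C:2](=O)O", "achiral",
    "ncaa", "", "none")
add("{Hyp}", "trans-4-hydroxy-L-proline",
    "[NH:1]1C[C@@H](O)C[C@H]1[C:2](=O)O", "L", "ncaa", "51-35-4", "S")
add("{Tic}", "L-1,2,3,4-tetrahydroisoquinoline-3-carboxylic acid",
    "[NH:1]1Cc2ccccc2C[C@H]1[C:2](=O)O", "L", "ncaa", "", "S")
add("{Pip}", "L-pipecolic acid", "[NH:1]1CCCC[C@H]1[C:2](=O)O",
    "L", "ncaa", "", "S")

df <- do.call(rbind, rows)
stopifnot(nrow(df) == 157L, !anyDuplicated(df$Token))

## reference canonical forms (OpenBabel), stored alongside -------------------
df$ReferenceCanonical <- canonical_smiles(df$`SMILES (CHUCKLES)`)

out <- file.path("inst", "extdata", "residue_library.csv")
write.csv(df, out, row.names = FALSE, na = "")
cat("wrote", out, ":", nrow(df), "entries\n")

## validation pass ------------------------------------------------------------
lib <- load_residue_library(out, validate = TRUE)
stopifnot(length(lib) == 157L)
cat("all entries pass validate_entry()\n")

## L/D pairs are enantiomers with equal formulas ------------------------------
pairs <- rbind(
  data.frame(l = setdiff(AA1, "G"), d = tolower(setdiff(AA1, "G"))),
  data.frame(l = sprintf("{%s}", vapply(NCAA, `[[`, "", 1)),
             d = sprintf("{d%s}", vapply(NCAA, `[[`, "", 1)))
)
for (i in seq_len(nrow(pairs))) {
  ls <- lib[[pairs$l[i]]]$smiles; ds <- lib[[pairs$d[i]]]$smiles
  stopifnot(identical(canonical_smiles(invert_stereo(ls)),
                      canonical_smiles(ds)))
  stopifnot(identical(formula_string(mol_formula(parse_smiles(ls))),
                      formula_string(mol_formula(parse_smiles(ds)))))
}
cat("all", nrow(pairs), "L/D pairs verified as enantiomers\n")

## RDKit cross-checks (development only) --------------------------------------
if (nzchar(Sys.which("python"))) {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(token = lib$entries$token,
                       smiles = lib$entries$smiles), tmp, row.names = FALSE)
  script <- 'import csv, sys
from rdkit import Chem
from rdkit.Chem import rdCIPLabeler
bad = 0
rows = list(csv.DictReader(open(sys.argv[1])))
for r in rows:
    m = Chem.MolFromSmiles(r["smiles"])
    if m is None:
        print("RDKIT-FAIL", r["token"]); bad += 1; continue
    rdCIPLabeler.AssignCIPLabels(m)
    cips = sorted(a.GetPropsAsDict().get("_CIPCode") for a in m.GetAtoms()
                  if a.HasProp("_CIPCode"))
    print(r["token"], Chem.MolToSmiles(m), ";".join(cips))
print("NBAD", bad)
'
  pyf <- tempfile(fileext = ".py"); writeLines(script, pyf)
  res <- system2("python", c(pyf, tmp), stdout = TRUE)
  stopifnot(any(grepl("^NBAD 0$", res)))
  # compare RDKit CIP multiset with ours
  res <- res[!grepl("^NBAD", res)]
  for (line in res) {
    parts <- strsplit(line, " ")[[1]]
    tok <- parts[1]
    rd <- if (length(parts) >= 3) sort(strsplit(parts[3], ";")[[1]]) else character()
    ours <- sort(stats::na.omit(assign_cip(parse_smiles(lib[[tok]]$smiles))))
    if (!identical(as.character(rd), as.character(ours))) {
      cat("CIP MISMATCH", tok, "rdkit:", rd, "ours:", ours, "\n")
    }
  }
  cat("RDKit CIP cross-check done\n")

  # canonical residues must equal RDKit's own one-letter builder
  script2 <- 'import sys
from rdkit import Chem
for a in sys.argv[1].split(","):
    m = Chem.MolFromSequence(a)
    print(a, Chem.MolToSmiles(m))
'
  pyf2 <- tempfile(fileext = ".py"); writeLines(script2, pyf2)
  res2 <- system2("python", c(pyf2, paste(AA1, collapse = ",")), stdout = TRUE)
  for (line in res2) {
    parts <- strsplit(line, " ")[[1]]
    mine <- canonical_smiles(lib[[parts[1]]]$smiles)
    ref <- canonical_smiles(parts[2])
    if (!identical(mine, ref))
      cat("SEQ MISMATCH", parts[1], mine, "!=", ref, "\n")
  }
  cat("RDKit canonical-residue cross-check done\n")
}
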