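# chuckles

Peptide assembly and graph featurization from CHUCKLES monomer notation.

Machine learning on peptides routinely needs molecule-level representations
— SMILES, molecular graphs, fingerprints — but most sequence tooling stops
at the 20 canonical L-amino acids. Therapeutic peptides do not: they carry
D-residues, noncanonical side chains, peptoid units, N-/C-terminal caps,
PEG spacers, and head-to-tail macrocycles. `chuckles` converts sequences
over all of these building blocks into atom-mapped SMILES, molecule
objects, and ML-ready arrays, driven by a user-editable residue library.

## The idea

Each monomer is stored as a SMILES string in **CHUCKLES** order — nitrogen
first, then the alpha carbon, then the C-terminal carboxyl — so that
peptide assembly reduces to string concatenation:

* every residue except the last loses the hydroxyl `O` of its `(=O)O`
  tail (the leaving group of condensation),
* every residue except the first has the hydrogen count of its leading
  nitrogen bracket decremented (`[NH2:1]` → `[NH:1]`),
* head-to-tail cycles additionally bond the first nitrogen to the last
  carbonyl carbon through a `%NN` ring-closure label.

Atom map 1 marks each backbone nitrogen and map 2 each carbonyl carbon, so
every peptide bond — and therefore every atom's residue of origin — is
recoverable from the assembled molecule. On top of that the package builds
the graph representation used by atom-level and hierarchical
(atom → residue) graph neural networks: an *n*×24 atom feature matrix
(optionally *n*×27 with CIP S/R/not-defined chirality columns), a
*bonds*×16 bond feature matrix, a 2×*E* adjacency, a per-atom residue
mapping vector, and per-residue L/D flags (`[1,0]` for L, `[0,1]` for D,
`[0,0]` for achiral units).

Tokens follow the residue library: one uppercase letter for L-amino acids
(`K`), one lowercase letter for D-amino acids (`k`), and `{...}` for
everything else (`{Aib}`, `{NPhe}`, `{ac}`, `{PEG2}`). The packaged default
library has 157 validated entries; any CSV/XLSX with `Token` and
`SMILES (CHUCKLES)` columns can replace it.

## Worked example

An acetyl-capped, amidated pentapeptide containing an achiral noncanonical
residue (Aib) and a D-lysine, assembled and featurized:

```r
library(chuckles)
lib <- load_default_library()

pep <- assemble_peptide("{ac}A{Aib}kW{am}", lib)
pep
#> <assembled_peptide> {ac}A{Aib}kW{am} [linear]
#>   C[C:2](=O)[NH:1][C@@H](C)[C:2](=O)[NH:1]C(C)(C)[C:2](=O)[NH:1][C@H](CCCCN)[C:2](=O)[NH:1][C@@H](Cc1c[nH]c2ccccc12)[C:2](=O)[NH2:1]
#>   38 atoms, 5 peptide bond(s)

canonical_smiles(pep$smiles)
#> [1] "NCCCC[C@H](C(=O)N[C@H](C(=O)N)Cc1c[nH]c2c1cccc2)NC(=O)C(NC(=O)[C@@H](NC(=O)C)C)(C)C"

g <- build_graph(pep, lib, include_chirality = TRUE)
g
#> <peptide_graph> 38 atoms x 27 features, 78 directed edges x 16 features, 6 residues

g$residue_flags
#>      [,1] [,2]
#> [1,]    0    0   # {ac}  achiral cap
#> [2,]    1    0   # A     L
#> [3,]    0    0   # {Aib} achiral
#> [4,]    0    1   # k     D
#> [5,]    1    0   # W     L
#> [6,]    0    0   # {am}  achiral cap
```

The atom-mapped SMILES keeps map 1 on every backbone nitrogen and map 2 on
every carbonyl carbon; `pep$residue_of_atom` assigns each of the 38 atoms
to one of the 6 residues (caps count as residues), and the 5 peptide bonds
are listed as (carbonyl C, amide N) atom pairs. `morgan_fingerprint(pep)`
returns the 2048-bit circular fingerprint (70 bits set here), and
`maccs_keys(pep)` the 166 MACCS keys.

Cyclic peptides use the same call with `cyclic = TRUE`
(`assemble_peptide("GG", lib, cyclic = TRUE)` gives
2,5-diketopiperazine), and `analog_triples()` generates matched
L / D / peptoid sequence sets. `export_graph()` writes a self-describing
JSON container (0-based indices) that PyTorch-Geometric-style loaders can
read without this package.

## Command line

```sh
exec/chuckles convert          --input seqs.csv --out-dir out/
exec/chuckles featurize        --input seqs.csv --out-dir out/ --chirality
exec/chuckles fingerprint      --input seqs.csv --out-dir out/ --kind morgan
exec/chuckles validate-library --library my_residues.csv
exec/chuckles make-analogs     --n 100 --seed 1 --out triples.csv
```

Each input row is processed independently: a bad row (unknown token,
malformed braces) is reported with its reason and the batch continues;
the exit status is nonzero if any row failed.

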