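---
title: "How chuckles assembles and featurizes peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How chuckles assembles and featurizes peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chuckles)
```

## The monomer contract

`chuckles` treats a peptide as a string program over a residue library.
Every monomer is written in CHUCKLES atom order — backbone nitrogen first,
alpha carbon second, C-terminal carboxyl last — with two atom-map
annotations: map 1 on the nitrogen (always the first atom written) and
map 2 on the carbonyl carbon. Residues that donate a C-terminus must end
in the literal free-acid tail `(=O)O`; N-caps carry map 2 only (they only
donate a carbonyl), C-caps map 1 only (they only accept one). The leading
nitrogen is always a bracket atom with an explicit hydrogen count
(`[NH2:1]`, or `[NH:1]` for proline and peptoids). That convention is what
makes assembly a pair of local string edits:

* *donating* residue: delete the final `O` of `(=O)O` — a safe edit
  because the tail is part of the library contract;
* *accepting* residue: decrement the bracket hydrogen count by one
  (`[NH2:1]` → `[NH:1]` → `[N:1]`). Bracket atoms carry no implicit
  hydrogens, so the count must be managed explicitly; an entry whose
  nitrogen has no hydrogen left (e.g. a tertiary-amine cap placed in the
  interior) fails with a "cannot accept a bond" error rather than
  producing a valence-broken molecule.

Head-to-tail cyclization applies both edits to the terminal residues as
well and inserts an unused two-digit ring-closure label (`%99` scanning
downward; two digits so that single-digit labels inside aromatic side
chains can never collide) immediately after the first residue's nitrogen
bracket and after the last residue's map-2 carbon bracket, before its
`(=O)` branch. Maps 1 and 2 are retained on the assembled molecule rather
than renumbered: residue membership is recovered *structurally*, by
cutting every bond that joins a map-2 carbon to a map-1 nitrogen and
reading off the connected components in concatenation order. This makes
the mapping robust to any future renumbering and gives the peptide-bond
list for free.

Within R, atoms and residues are indexed 1-based; `export_graph()`
serializes 0-based (and records `index_base` in the metadata) because the
downstream consumers are Python graph-learning loaders.

## The SMILES layer

The package includes its own SMILES reader and writer, covering the
dialect the library is written in: organic-subset and bracket atoms,
aromatic lowercase notation, charges, atom maps, branches, ring closures
(`1`–`9`, `%NN`), and tetrahedral `@`/`@@` tags. This is deliberate: the
assembly rules above are defined *on the string*, the featurizer needs
per-atom access to maps, hydrogen counts and stereo parity, and no
installed R package exposes that level of molecular detail. Three
boundaries keep the hand-rolled part honest:

* **Canonicalization is delegated.** `canonical_smiles()` and
  `mol_inchi()` call the OpenBabel converter; the package never claims
  its own canonical form. Canonical SMILES is the equality oracle for
  small molecules; for long chains (beyond roughly twenty residues)
  OpenBabel's canonical labeling becomes pathologically slow while its
  InChI generation does not, so long-sequence identity checks use the
  standard InChI, whose stereo layer (`/m0` vs `/m1`) also distinguishes
  enantiomers.
* **Fingerprints are delegated** to OpenBabel's ECFP and MACCS
  implementations (through ChemmineOB).
* **The test suite cross-checks everything** against two independent
  toolkits: assembled canonical forms against RDKit's own one-letter
  sequence builder, and CIP labels against RDKit's modern CIP
  implementation, over the whole library and random assembled peptides.

Deliberate exclusions of the dialect: dot-disconnected SMILES, isotopes,
wildcard atoms, and directional `/ \` bonds are rejected at parse time.
The packaged residue space contains no E/Z double bonds, so the
bond-feature stereo block (below) always lands in its "none" column; a
library needing cis/trans side chains would require extending the reader.

Implicit hydrogen counts follow standard SMILES valence rules (B 3, C 4,
N 3/5, O 2, P 3/5, S 2/4/6, halogens 1, adjusted by charge); aromatic
carbons receive one hydrogen when two-connected, aromatic N/O/S none
(pyrrole-type nitrogen must be written `[nH]`).

## CIP chirality assignment

The three optional chirality columns (S, R, not defined) come from a CIP
assignment computed on the assembled molecule, not copied from the
library. Substituent priority is decided by hierarchical sphere-by-sphere
comparison of atomic numbers with duplicate ("phantom") atoms for double
and triple bonds and for ring closures; an aromatic atom receives one
phantom carrying its heaviest aromatic neighbor's atomic number, standing
in for the Kekulé duplicate. The descriptor follows from the permutation
parity between the neighbor order written in the SMILES and the priority
order. Comparison depth is capped at twelve spheres — far beyond any
priority decision arising in this chemical space.

This implements CIP rule 1a with a practical rule-1b treatment. The
higher rules (isotopes; the stereo-dependent rules 4–5 needed for
meso-type dependencies) are *not* implemented: they cannot be triggered
by the packaged residue space, and a tagged atom whose substituents tie
under the implemented ranking is reported "not defined" rather than
guessed. Atoms with no tetrahedral tag are likewise "not defined",
matching the third category of the feature layout. A worth-knowing
subtlety found while validating: RDKit's *legacy* stereo-perception
mislabels cysteine-type centers (sulfur-containing side chains); the
cross-checks therefore use its modern CIP labeler, which agrees with this
package on every library entry.

## Feature layouts

The atom feature matrix has exactly 24 columns: element one-hot over
{C, N, O, S, F, Cl, Br, P, Se, other} (10), heavy-atom degree one-hot
{1, 2, 3, 4, other} (5), total-hydrogen one-hot {0, 1, 2, 3} (4), formal
charge as a scalar (1), aromatic flag (1), ring flag (1), and
hybridization one-hot {sp2, sp3} (2; sp and exotic states map to zeros,
and neither occurs in the packaged space). The element vocabulary covers
every element in the default library; an out-of-vocabulary element raises
an error that names it and points to the `extra_elements` argument plus a
custom library, rather than silently zero-filling. Hybridization is
derived from bond orders (aromatic or one double bond → sp2; otherwise
sp3), a deliberately structural definition — it classifies amide nitrogen
as sp3 where a resonance-aware model would say sp2, but it is computable
without electronic-structure heuristics and is consistent across the
library.

The bond feature matrix has exactly 16 columns: bond-type one-hot
{single, double, triple, aromatic} (4), conjugation flag (1), ring flag
(1), stereo one-hot {none, Z, E, other} (4), peptide-bond flag (1,
exactly the bonds in the assembled peptide's bond list), intra-residue
flag (1, from the residue mapping), rotatable flag (1), and
smallest-ring-size one-hot {5, 6, other} (3, zero for acyclic bonds). A
single bond is conjugated when both ends participate in a pi system or
carry a lone pair next to one (which marks the amide C–N bond, ester and
phenol C–O, and aromatic attachments, but not isolated carbonyls);
rotatable means a non-ring single bond between two non-terminal heavy
atoms that is not an amide bond. Ring perception uses bridge detection on
the molecular graph (a bond is in a ring iff it is not a bridge), and the
smallest ring through a bond is the shortest alternative path between its
endpoints plus one.

Adjacency is reported as a 2×E integer matrix; with
`directed_duplication = TRUE` (the default, since message-passing
frameworks consume directed edge lists) each bond appears in both
directions and its feature row is duplicated, E = 2×bonds.

## Fingerprints

`morgan_fingerprint()` maps radius *r* to OpenBabel's ECFP(2*r*) plugin
(default radius 2, the ECFP4 equivalent — the conventional choice where
no radius is specified) and folds the fixed 4096-bit output to `n_bits`
(default 2048) by index modulo; radius above 5 has no plugin and errors.
`maccs_keys()` returns the standard 166-key dictionary — OpenBabel pads
its bit vector to 256-bit words, and the padding is verified empty before
truncation. The length is recorded in an attribute because MACCS length
is occasionally misreported in the literature; 166 is what the standard
SMARTS dictionary defines. Both fingerprints are functions of the
molecular constitution only: an L-peptide and its D-mirror are
indistinguishable to them (a pinned regression fact in the tests), which
is precisely why the graph representation carries explicit chirality
columns and per-residue L/D flags.

## The analog generator

`random_l_sequences()` emulates the randomized study design used to probe
how learned embeddings organize stereo- and constitutional isomers: *n*
sequences (default 100) with lengths uniform on [5, 30] and residues
uniform over the 18 canonical letters excluding proline and glycine,
which have no peptoid analog — proline's nitrogen is in the ring, and an
N-substituted glycine derived from glycine is glycine itself. Uniform
distributions are the natural reading of "random" absent any stated
weighting; the generator is seeded for reproducibility.
`to_d()` lowercases (the library's D convention) and `to_peptoid()` maps
each letter to its `{NXxx}` entry, in which the side chain sits on the
backbone nitrogen. Every triple therefore shares one molecular formula;
L/D are enantiomers (InChI differing only in the mirror flag) and the
peptoid is a distinct constitutional isomer — all verified per-triple in
the acceptance script.

What the generator does *not* emulate: real peptide datasets' length and
composition biases, homopolymeric stretches' solubility limits, or any
property labels. Passing tests show the *representations* are correct and
self-consistent, not that any downstream model will predict well from
them.

## The default library

The packaged library holds 157 entries: the 20 canonical L-amino acids,
their 19 D-isomers, 18 peptoid analogs, 18 N-methyl variants, six end
caps (acetyl, formyl, benzoyl; amide, N-methylamide, N,N-dimethylamide),
four amino-PEG acids, and 72 further noncanonicals (30 L/D pairs of
common residues — ornithine, citrulline, halogenated phenylalanines,
pyridylalanines, selenocysteine, and so on — plus 12 achiral or
single-stereoform entries such as Aib, beta-alanine and
trans-4-hydroxyproline). Each entry stores its expected alpha-carbon CIP
code (S for L-residues, R for D — with the cysteine/selenocysteine
inversion stored per entry rather than special-cased in code) and an
OpenBabel reference canonical SMILES used by the round-trip tests.
`validate_entry()` re-derives, for any entry: parseability, map
placement, the acid tail, the alpha CIP code, and a parse→write→parse
stereo round trip; failures are reported per check, not raised, so a
library audit sees all problems at once.

## Problem sizes and determinism

The randomized suites run at sizes that exercise every code path while
keeping a full check fast: 200 random canonical sequences (lengths 1–10)
for the converter-equivalence oracle, 200 full-library sequences (up to 8
residues plus caps, alternating linear/cyclic) for formula conservation
and mapping correctness, 50 L/D pairs for enantiomer symmetry, and 25
analog triples at the full study lengths 5–30. All random draws flow from
a single seed argument; batch outputs are byte-reproducible for a fixed
configuration.

## Known limitations

* No side-chain-to-side-chain or side-chain-to-terminus cyclization
  (disulfides, lactam staples): head-to-tail only.
* No E/Z double-bond stereochemistry in the residue dialect.
* No 3D: conformers, and any feature needing geometry, are out of scope.
* Canonical SMILES of very long assemblies is slow in the underlying
  toolkit; prefer `mol_inchi()` for identity checks on long peptides.
* CIP assignment is complete only for the rule subset described above;
  exotic user libraries could construct centers it declines to label
  (reported "not defined", never mislabeled silently).
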