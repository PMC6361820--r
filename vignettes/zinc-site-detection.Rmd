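---
title: "Detecting and clustering zinc binding sites in protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and clustering zinc binding sites in protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincsites)
```

## The problem

Zinc ions appear in crystal structures for many reasons besides biology:
they arrive with the crystallisation buffer, they sit on special symmetry
positions, and their apparent coordination shell depends on which copy of
the molecule the depositors chose to place in the asymmetric unit. A
catalogue of *biologically relevant* zinc sites therefore needs three
things a naive distance search does not provide: generation of the
biological assembly before measuring anything, a principled definition of
a coordinating (liganding) atom, and a salt filter that discards
adventitious ions. Once sites are identified, the heavy redundancy of the
PDB (hundreds of near-identical depositions of popular enzymes) must be
collapsed so that statistics describe distinct sites rather than
deposition frequency. `zincsites` implements this pipeline end to end.

## The detection model

**Assembly.** REMARK 350 instructions are parsed into rotation/translation
groups. Among declared assemblies whose chains carry a zinc, the one with
the lowest solvent-free-energy annotation (the PISA "CHANGE IN SOLVENT
FREE ENERGY" line, the only energy the PDB format itself records) is
selected; when no energy is annotated the first-listed zinc-containing
assembly is used, and when the file declares no assemblies the asymmetric
unit is processed as-is. This fallback chain is a design choice: the
format guarantees neither an energy annotation nor its provenance, so a
deterministic, documented rule was preferred over guessing. Expansion is a
rigid transform per chain copy; every atom keeps its source identifier
(chain, residue number + insertion code, atom name), which later drives
symmetry deduplication and the zinc accounting.

**Liganding rule.** For each metal, candidate liganding atoms are all
non-carbon, non-hydrogen, non-metal atoms within `cutoff` of the metal
centre. The cutoff defaults to 3.0 Å and is *inclusive* — a donor at
exactly 3.0 Å coordinates. Within each residue, candidates are considered
nearest-first and one is discarded when the angle it subtends at the metal
with any closer retained atom of the same residue falls below `min_angle`
(default 45°, *strict*: exactly 45° is kept). The angle vertex is the
metal because no other vertex is computable without bond topology, and the
comparison is restricted to atoms of the same residue: the rule exists to
stop one side chain from contributing two nearly collinear atoms (e.g. a
carboxylate oxygen plus its neighbour), while a genuine bidentate
aspartate, whose two oxygens subtend ~50–70° at the zinc, keeps both.
Whether atoms of *different* residues should also compete was left open by
the rule's usual statement; this implementation compares within a residue
only, which is the reading that preserves interface sites built from many
single-atom donors.

**Metal grouping and salts.** Metals sharing at least one liganding
residue are merged transitively (union-find) into one site — this is what
makes a histidine-bridged Zn/Cu pair a single co-active unit. Groups
without a zinc are dropped. Each zinc is then tested against the salt
thresholds: at least `min_protein_residues = 2` distinct protein liganding
residues and `min_protein_atoms = 3` protein liganding atoms. Waters and
hetero ligands never count toward either threshold, so a zinc held by one
bidentate aspartate and one histidine (2 residues, 3 atoms) passes while a
zinc in a shell of waters and chloride does not. A site is stored when at
least one of its zincs passes; otherwise each zinc receives one exclusion
record. Exclusion reasons are assigned with a fixed precedence — no
side-chain information (Cα/backbone-only model), not in the biological
assembly, too few liganding residues, too few liganding atoms — so each
zinc carries exactly one reason and residue count is tested before atom
count.

**Symmetry duplicates and copy counting.** A zinc on a rotation axis
expands to coincident copies; among copies sharing a source identifier
within `duplicate_tolerance = 0.5` Å of one another, only the lowest copy
index survives. The tolerance has a wide safe band: numerically coincident
copies differ by far less than 0.5 Å, genuine neighbouring ions by at
least a bonding distance (> 2 Å). Conversely, when an assembly duplicates
a whole site (two transforms of the same chain), the duplicates have
identical source identifiers for metals and residues; they are merged into
one stored site whose `copies` counter records the multiplicity.

**Accounting identity.** Every zinc atom deposited in a file ends in
exactly one of: membership of a stored site, or one exclusion record. The
test suite and the acceptance script verify this identity on every fixture.

## Redundancy removal

Chains that contribute protein liganding residues are clustered at 90 %
sequence identity with a greedy incremental algorithm in the style of
CD-HIT, re-implemented here rather than shelled out so that the package
has no external binary dependency: chains are sorted by decreasing length
(ties by chain key), and each joins the first cluster whose
*representative* it matches at or above the threshold (inclusive), else
seeds a new cluster. Identity is computed from a global alignment (match
+1, mismatch 0, gap −1, via `Biostrings::pairwiseAlignment`) as matches
divided by the shorter sequence's length — the CD-HIT convention.
Comparing to the representative rather than to all members is a documented
choice; the planted-family recovery test shows it reproduces the intended
partition under realistic within-family divergence.

Two sites are equivalent when (i) the multisets of chain clusters of
their liganding chains match, (ii) the liganding residue one-letter types
occur in the same order along each chain and (iii) the residues at
sequence positions ±1 of every liganding residue have the same types,
with `-` encoding a chain terminus so that termini never match a residue.
Condition (i) is read as a multiset so homodimer interface sites compare
independently of chain labels. Waters and hetero ligands are excluded
from fingerprints — the equivalence conditions are about amino acids.
Within each fingerprint class the member from the best-resolution
structure is the representative; a missing resolution (NMR) sorts as +∞
and ties go to the lexicographically smallest PDB id.

## Statistics

* **Residue signature**: one-letter codes of the protein liganding
  residues with counts, letters alphabetical (`C3H1`, count suffix always
  present). Totals over a site set always equal the number of sites.
* **Coordination mode**: contact count of the zinc in single-zinc sites,
  *including* waters — a coordinating water is part of the sphere even
  though it never counts toward the salt thresholds. Multi-zinc sites are
  outside the operation's domain and raise an error.
* **Distance statistics**: per-element mean and sample (n−1) standard
  deviation of contact distances, pooled over single-zinc sites from
  structures with resolution *strictly better* than 3 Å. The sample SD is
  a convention choice; at the pool sizes involved the difference from the
  population SD is negligible.
* **Co-active table**: per element, multi-metal sites contribute each
  non-zinc atom once and each zinc beyond the first once (a three-zinc
  site adds +2 to zinc), alongside the count of sites containing the
  element and a metals-per-site histogram.
* **Enzymatic enrichment**: a molecule name is enzymatic when any
  whitespace token of its lower-cased form ends in "ase". The 2×2
  contingency of (multi-metal vs zinc-only) × (enzymatic vs not) is
  tested with the two-sided Fisher exact test (`stats::fisher.test`,
  p = sum of table probabilities not exceeding the observed table's);
  tests validate it against explicit log-space enumeration of all tables
  with the observed margins.

## The synthetic generator

`make_fixture()` writes valid fixed-column PDB text for nine scenarios
(salt, Cys4 site, bidentate carboxylate, exact-angle probe, interface
assembly, co-active multi-metal, duplicated asymmetric unit,
backbone-only, sequence families), each with a ground-truth record built
*constructively during generation* — expected sites, signatures, copies
and exclusion reasons are known from the geometry being placed, never
obtained by running the detector on its own output. Per seed, ligand
distances are drawn from narrow truncated normals around canonical
values (Zn–S 2.33 Å, Zn–N 2.10 Å), ligand directions are randomly
oriented, and the whole structure receives a random rigid motion (with
assembly transforms conjugated into the new frame), so passing tests
demonstrate invariance to pose and to benign metric variation. Nothing a
rule depends on is ever sampled across its decision boundary.

What the generator does *not* emulate: full side-chain rotamers (only
rule-relevant atoms plus enough backbone for residue typing and sequence
context are placed), crystallographic disorder, alternate conformations
beyond the dedicated altloc tests, chemically realistic ligand geometry,
or the composition biases of the real PDB. Green tests therefore show the
*rules* are implemented exactly as specified, not that real-PDB summary
numbers would be reproduced; those depend on a corpus snapshot.

## Numerical and degenerate-input choices

* Distance cutoff inclusive (≤ 3.0 Å); angle rule strict (< 45°
  discards); resolution filter strict (< 3.0 Å qualifies).
* Alternate locations: highest occupancy wins, ties go to the
  alphabetically first altloc ('A'). Multi-model files: first model only.
* Backbone-only means no protein residue has a heavy atom outside
  {N, CA, C, O, CB, OXT}; OXT is main-chain, not side-chain.
* Coordinates are treated as orthogonal Å; no crystallographic symmetry
  beyond the declared assembly transforms is generated.
* Empty structures, unknown chains in assembly instructions, empty
  sequences, zero-margin contingency tables and multi-zinc coordination
  queries raise errors rather than guessing.
* Chain clustering is deterministic under permutation of equal-length
  inputs (ties broken by chain key); metal groups are ordered by their
  smallest member's source identifier.

## Validation problem sizes

The shipped validation runs the detector against constructive ground
truth for 8 scenario configurations × 100 seeds (800 structures), checks
union-find metal clustering against brute-force transitive closure on 500
random instances of up to 12 metals, probes the angle rule at
θ ∈ {30, 44.9, 45, 60, 109.5}°, recovers planted chain families for
k = 2…6 (8 chains of length 80 per family, ≤ 5 % mutations), and checks
the Fisher implementation against exhaustive enumeration over all 2×2
tables with total n ≤ 30 plus 500 random larger tables. These sizes give
full coverage of every rule and branch while keeping a complete run in
the low tens of seconds on one CPU.

## Limitations

Site *prediction* in apo structures is out of scope, as are mmCIF
parsing, crystallographic (SMTRY) symmetry expansion, metal sites without
any zinc, and bit-compatibility with CD-HIT's word-filter heuristics.
Whole-PDB statistics require a PDB snapshot and a network, which this
package deliberately does not assume; the `build_database()` batch path
is the same code that would process such a snapshot.
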