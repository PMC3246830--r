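---
title: "Searching crystal-structure databases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching crystal-structure databases: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalsearch)
```

This vignette is the package's own account of the science behind its four
search engines: the models and their assumptions, the parameters that
matter, what the synthetic fixtures do and do not establish, and the design
choices made where the design was genuinely open. Everything quantitative
shown here is computed by the code at build time of the examples; nothing
is quoted from elsewhere.

## 1. The chemical model

Molecules are **hydrogen-suppressed 2D connectivity graphs**: atoms carry
an element symbol and a formal charge, bonds carry a Kekulé order (single,
double, triple). There is no aromatic bond type — aromatic rings are
represented in a fixed Kekulé form — and no stereochemistry or geometry.
The hydrogen model deserves a note: nothing in the problem statement fixes
whether matching and fingerprinting should see explicit hydrogens, so the
package adopts the mainstream convention of connectivity search systems and
removes explicit H atoms at database build time (a `retain_h` flag keeps
them). A consequence the user should expect: a query cannot distinguish
protonation states except through formal charges.

Ring perception produces three artifacts:

* a **smallest set of smallest rings** (minimum cycle basis). Cycle bases
  are not unique; for determinism the candidate cycles (Horton's set:
  shortest cycles through each vertex/edge pair, from BFS trees that visit
  neighbors in ascending index order) are sorted by (size, lexicographic
  atom tuple) and selected greedily under GF(2) independence. For a
  connected graph the basis size is always |bonds| − |atoms| + 1.
* **smallest ring size through every atom and bond**, computed
  *independently* of the basis choice by a per-bond BFS (remove the bond,
  find the shortest path between its endpoints). This is the quantity ring
  constraints test, so it must not depend on which SSSR was selected.
* **ring assemblies**: connected components of the subgraph of ring bonds.
  Because components connect through shared atoms as well as shared bonds,
  fused systems (naphthalene) and spiro systems (spiro[4.5]decane) each
  form a single assembly; the assembly's size in atoms drives the
  macrocycle screen below.

```{r rings}
ri <- compute_ring_info(parse_linear("C1CCCC12CCCCC2"))  # spiro[4.5]decane
lengths(ri$rings); ri$max_assembly
```

## 2. Path fingerprints and similarity

Each connectivity is summarized by a **2040-bit binary fingerprint**. The
feature set is every simple bonded path of 1–10 atoms, encoded as an
alternating string of atom tokens (element plus a charge suffix when
nonzero, e.g. `N+1`) and bond symbols (`-`, `=`, `#`), read in whichever
direction is byte-wise smaller. Features are hashed with 32-bit FNV-1a and
folded modulo 2040; exactly one bit per feature, set-not-counted.

Parameter notes, with defaults and why:

* **Width 2040 bits** is the fixed, field-standard width for this family of
  fingerprints; it is configurable per database (`fp_width`) but both
  search engines refuse to mix settings, since bit positions are only
  comparable within one width. Why the historical width is 2040 rather
  than a power of two is not documented anywhere we know of; the package
  uses a flat 2040-bit space with no partitioning by path length.
* **Path cap 10 atoms** bounds feature length; longer paths add little
  discrimination at substantial cost. A linear C20 alkane therefore
  produces its longest feature at exactly 10 atoms.
* **Hash choice.** The original system's exact bit assignment is not
  recoverable, so published coefficient values for specific compound pairs
  can only be reproduced *qualitatively* (same ranking, similar
  magnitudes), never bit-exactly. FNV-1a/32 was chosen because it is
  trivially portable, well distributed for short ASCII strings, and exactly
  representable in R doubles; the implementation is frozen against an
  independently computed golden table in the tests.

Two standard coefficients compare fingerprints: Tanimoto
$T = |A\cap B| / |A\cup B|$ and Dice $D = 2|A\cap B|/(|A|+|B|)$, both in
$[0,1]$ with $T \le D$ always. Two all-zero fingerprints score 1 — they are
identical representations — with a warning, since any non-empty molecule
sets at least one bit.

The fingerprints inherit well-known caveats, which the package treats as
*testable properties* rather than defects: they are cyclicity-blind
(hexane and cyclohexane are bit-identical — path sets coincide), they are
element-based (chemically similar halogens or transition metals are
distinct), and small molecules with few paths are weakly characterized and
prone to low coefficients.

```{r fp}
identical(fingerprint(parse_linear("CCCCCC"))$bits,
          fingerprint(parse_linear("C1CCCCC1"))$bits)
```

## 3. Substructure search

A query is an annotated linear-notation graph: `*` matches any element,
`~` any bond order, `{ring:MIN-MAX}` / `{ring:acyclic}` constrain the
smallest ring through an atom or bond, `{charge:±n|any}` constrains formal
charge. Compilation derives three **screens** — necessary conditions that
are cheap to test against precomputed per-connectivity data:

1. element multiset containment (non-wildcard query atoms);
2. fingerprint-bit containment for *fully definite* query paths (no
   wildcard atom, no any-order bond, no unconstrained charge on the path);
3. if the query contains a ring, its largest ring assembly must not exceed
   the connectivity's (a 12-membered macrocyclic query can never match a
   database whose largest assembly has 10 atoms).

Soundness — a screen may never reject a true match — is the design
invariant, checked on a 1,000-pair randomized sweep. It forced one
interface decision worth recording: **a plainly written query atom
constrains charge to zero**, with `{charge:any}` available for
charge-agnostic matching. Had plain atoms matched any charge (as some
query languages do), a plain `C=N` query could match a charged nitrogen
whose features carry a charge suffix and hash elsewhere, and the feature
screen would wrongly reject the entry; charge-0-by-default keeps the
screen both sound and non-trivial, at the cost of requiring an explicit
annotation for charge-insensitive queries.

Matching itself is subgraph **monomorphism** (extra bonds in the target are
allowed, so an acyclic-drawn query embeds in a ring unless a ring
constraint forbids it), found by a breadth-first candidate-list algorithm:
per-query-atom candidate lists filtered by element/charge/degree/ring
predicates, iterative adjacency refinement to a fixed point (a candidate
survives only while every neighboring query atom retains a compatible
candidate), then backtracking assignment in most-constrained-first order.
Automorphic duplicate mappings are deliberately kept in `find_all` mode —
mapping counts are then exact and comparable with an exhaustive oracle.
Existence mode stops at the first embedding.

## 4. Reduced-cell search

A lattice has one canonical **Niggli reduced cell**, computed here with the
Krivý–Gruber iteration on the metric scalars. Floating-point comparisons
use a stabilizer ε = 10⁻⁵·V^(2/3); the change of basis is tracked as an
integer matrix of determinant ±1 and the metric is recomputed from it each
step, so the scalar state can never drift from the transformation. The
iteration is bounded (error after 1000 steps, unreachable for valid
metrics); reduction is idempotent and volume-preserving to 10⁻⁸ relative.

The reduced *angles* are numerically unstable: near decision boundaries a
tiny perturbation of the input can flip the reduction into a different
representative (e.g. an 89.9° angle versus its 90.1° alternative). A
search that compared single reduced cells would therefore miss near-
boundary matches, while one that compared only lengths would admit false
positives. The package follows the nearly-Buerger strategy: the query's
reduced basis is expanded through all unimodular matrices with entries in
{−1,0,1}, keeping images that still satisfy the Buerger shortest-vector
conditions within tolerance and whose parameters stay inside an
instability window of **2×** the matching tolerance around the Niggli
parameters. Far from boundaries this set has size 1; near a 90° boundary
it acquires the alternative representatives. A candidate matches if *any*
member agrees on all three lengths (relative tolerance, default **1%**)
and all three angles (absolute, default **1.0°**), trying the axis
permutations that respect length-ordering ties. The exact enumeration
bound and window factor are this package's own construction — the
literature's parameterization is not reproduced here — chosen so that the
set is finite, exhaustively testable, and provably contains the Niggli
cell; the angle-aware hit set is asserted in tests to be a subset of the
lengths-only hit set and to exclude engineered equal-length decoys. Default
tolerances are deliberately tight for a "have I already measured this
crystal?" workflow; both are configurable per search.

## 5. The store

The database is a single file of documented relational tables
(`docs/SCHEMA.md`): entry metadata; serialized connectivities;
per-connectivity fingerprints, element multisets and ring-assembly sizes;
raw and reduced cell parameters; and an inverted text index. Everything
derived is computed once at build time — searches only read. Tokenization
is lowercase with splits at every non-alphanumeric character, no stemming
and no stop words, so hyphenated chemical nomenclature fragments into
searchable tokens (`"…-thiadiazine-1,1-dioxide"` yields `thiadiazine`);
postings keep token positions so multi-token terms are verified as true
phrases. Dates are ISO-8601 strings, compared lexicographically, ranges
inclusive. Composite queries are conjunctions only (AND); OR/NOT are out
of scope. The serialization container (R's native format rather than an
external database engine) was chosen to keep the package dependency-free;
the schema, not the container, is the contract, and index lookups are
asserted equal to full linear scans in the tests.

## 6. Synthetic fixtures: what a green test establishes

The fixture generator emulates the *structure* of a small crystallographic
database: 20 entries with refcodes, molecules, cells and metadata. Its
fixed catalog carries the analytically known cases (hexane/cyclohexane,
C20, macrocycle, spiro and fused systems, halobenzenes) and a drug-analog
family — three simplified Kekulé scaffolds sharing a
benzimidazole–sulfinyl–pyridine core, standing in for real anti-ulcerative
drugs whose full structures are not bundled — plus five unrelated decoys.
Random molecules are spanning trees with up to two ring closures (each
added with probability 0.4), elements drawn C-rich from {C,N,O,S,Cl,F},
bond orders 80/15/5% single/double/triple, and ±1 charges on 5% of N/O
atoms: typical shapes and sizes for small-molecule organic chemistry, kept
at ≤ 12 atoms so exhaustive matching oracles stay feasible. Cells are
drawn in a near-reduced parameterization (lengths 4–15 Å sorted, angles
70–115°), with designated extras: a scrambled-basis lattice duplicate, a
near-90° boundary cell, and an equal-lengths angle decoy.

What the fixtures do **not** contain: real crystal structures, realistic
space-group statistics, disorder, polymers, organometallics at realistic
frequency, or text fields with natural-language scale. A green suite
therefore establishes algorithmic correctness (against brute-force oracles
and analytic identities) and contract compliance — not retrieval quality
on any real database, and not the licensed reference numbers of the
original portal, which are unreproducible without its content.

## 7. Numerical and degenerate-input choices

* FNV-1a arithmetic is done in doubles with an exact split-multiply mod
  2³²; verified against an independent implementation.
* Canonical path direction uses byte order via radix sorting, immune to
  locale collation.
* `unit_cell` rejects non-positive-definite metrics at construction;
  `niggli_reduce` additionally guards against degenerate input.
* Cell matching compares sorted lengths and tries all axis permutations,
  so a = b ties cannot cause false negatives.
* Empty molecules cannot be fingerprinted (error); metadata-only entries
  are stored with a warning and simply never hit in structural searches.
* The SSSR tie-break, BFS orders, and backtracking order are all fixed, so
  every derived artifact — and thus a rebuilt database — is deterministic.

## 8. Known limitations

No aromaticity perception (Kekulé-form-sensitive queries must use `~`
bonds), no stereochemistry, no 3D or intermolecular constraints, no
sub-/super-cell lattice relations, no OR/NOT in composite queries, no
count-based or generalized (element-equivalence) fingerprints. Matching
performance targets molecules of typical small-molecule size; the
exhaustive-enumeration oracles in the tests, not the engines, are the
limiting factor for large graphs.
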