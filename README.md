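# xtalsearch

Search engines for local databases of small-molecule crystal-structure
entries, in pure R. The package is aimed at crystallographers and
cheminformaticians who want the four classic search modes of a structural
database portal — 2D substructure, molecular similarity, text/numeric
fields, and reduced unit cell — as a scriptable library plus a command-line
tool, operating on databases built from SDF/CIF input or on fully synthetic
fixtures (no external data needed).

## What is inside

* **Chemical model** — hydrogen-suppressed molecular graphs (Kekulé bond
  orders 1–3, formal charges), deterministic SSSR ring perception,
  smallest-ring sizes per atom/bond, fused/spiro ring assemblies; readers
  and writers for V2000 SDF/MOL, a SMILES-like linear notation, and minimal
  CIF cell blocks.
* **Similarity** (`fingerprint`, `similarity_search`) — for each
  connectivity, a fixed-width **2040-bit** fingerprint over all simple
  bonded paths of up to **10 atoms**, each path encoded as a canonical
  `element(bond)element…` string and hashed with 32-bit FNV-1a. Scores are
  the Tanimoto |A∩B|/|A∪B| and Dice 2|A∩B|/(|A|+|B|) coefficients, both in
  [0, 1]. By construction the fingerprints are cyclicity-blind (hexane ≡
  cyclohexane) and element-based (F ≠ Cl) — known caveats that the test
  suite asserts as properties.
* **Substructure** (`compile_query`, `substructure_search`) — queries in an
  annotated linear notation (`*` wildcard, `~` any bond, `{ring:MIN-MAX}`,
  `{ring:acyclic}`, `{charge:±n|any}`), compiled into a query graph plus
  sound necessary-condition screens (element multiset, definite path
  feature bits, largest ring-assembly size), then matched by a
  breadth-first backtracking subgraph-monomorphism search with candidate
  refinement. Screens change speed, never results.
* **Reduced cell** (`niggli_reduce`, `reduced_cell_search`) — Krivý–Gruber
  Niggli reduction with epsilon-stabilized comparisons, expansion of a
  query into its "nearly Buerger reduced" neighbor cells, and angle-aware
  tolerance matching (default 1% on lengths, 1.0° on angles) that rejects
  lattices a lengths-only comparison would conflate.
* **Store** (`build_database`) — a single-file database with documented
  relational tables (see `docs/SCHEMA.md`): everything derived is
  precomputed at build time, and text fields are tokenized into an
  inverted index with positional postings for token, phrase, numeric,
  date-range and composite (AND) queries.
* **Fixtures** (`catalog_molecules`, `fixture_entries`, `build_fixture_db`)
  — deterministic synthetic entries with a ground-truth manifest, so every
  search mode is testable offline.

## Worked example

```r
library(xtalsearch)

fx <- fixture_entries(fixture_spec(seed = 1))   # 20 synthetic entries
db <- build_database(fx$entries)

# similarity: an omeprazole-like query against the fixture database
query <- catalog_molecules()$omeprazole_analog
similarity_search(query, db, "tanimoto", top_k = 5)
#>   refcode connectivity coefficient
#> 1  FIX002            1  1.00000000
#> 2  FIX001            1  0.81049563
#> 3  FIX003            1  0.75741240
#> 4  FIX005            1  0.09116022
#> 5  FIX017            1  0.08684864
```

`FIX002` is the query's own entry (coefficient 1); the next two hits are
the other members of the benzimidazole–sulfinyl drug-analog family, far
above every unrelated decoy — the qualitative behavior expected of
scaffold-level path fingerprints.

```r
# substructure: a C=N double bond whose carbon sits in a six-membered ring
r <- substructure_search("C{ring:6-6}=N", db)
r
#>   refcode connectivity n_mappings
#> 1  FIX001            1          1
#> 2  FIX002            1          1
#> 3  FIX003            1          1
#> 4  FIX011            1          1
attr(r, "counts")
#> $screened_out [1] 13   $matched [1] 4   $searched [1] 8
```

Thirteen of 21 connectivities were discarded by the precomputed screens
without any graph matching; the four hits are the three analogs (imidazole
C=N, carbon fused into the benzo ring) and pyridine.

```r
# reduced cell: angle-aware search rejects the equal-lengths decoy
reduced_cell_search(unit_cell(5, 6, 7, 80, 85, 88), db)
#>   refcode red_a red_b red_c red_alpha red_beta red_gamma
#> 1  FIX003     5     6     7        80       85        88
```

The database also contains `FIX004` with identical reduced lengths but
angles ~10° away; a lengths-only search (`lengths_only = TRUE`) returns
both, the angle-aware default returns only the true lattice.

```r
# composite text query: needle habit AND phase transitions recorded
run_composite(db, list(fq_text("habit", "needle"), fq_defined("phase_transitions")))
#> [1] "FIX001" "FIX009"
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "xtalsearch", package = "xtalsearch"))')
Rscript $CLI fixtures --out fx/
Rscript $CLI build --entries fx/entries.tsv --out db.xdb
Rscript $CLI simsearch  --query "C1=CC=CC=N1" --db db.xdb --coeff dice --top-k 5
Rscript $CLI subsearch  --query "C{ring:6-6}=N" --db db.xdb --count-matches
Rscript $CLI cellsearch --cell "5,6,7,80,85,88" --db db.xdb
Rscript $CLI textsearch --db db.xdb --field habit --term needle --and "phase_transitions:*"
```

Results go to `--out` (TSV) or stdout; screening/matching counts go to
stderr. Exit codes: 0 success, 1 data error, 2 usage error.

## Documentation

The methods vignette (`vignettes/crystal-structure-searching.Rmd`) explains
the models, parameters, numerical choices and limitations; `docs/SCHEMA.md`
documents the database schema.
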