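# xtalsearch database schema (schema_version 1)

A database file is a single-file serialized container (`saveRDS`, version 3)
holding the object described below. The schema — table names, columns and
their meaning — is the stable contract; the serialization container is an
implementation detail.

```
xtal_db
├── schema_version   integer (currently 1)
├── config           fp_width (2040), max_path_atoms (10),
│                    rel_length (0.01), abs_angle (1.0)
└── tables
    ├── entries          one row per entry, ordered by refcode
    │     refcode, authors, journal, compound_name, synonyms, habit,
    │     bioactivity, phase_transitions, polymorphism,
    │     year, volume, first_page          (integers, NA allowed)
    │     date_added, date_modified         (ISO-8601 strings, NA allowed)
    ├── connectivities   one row per connectivity (refcode, connectivity)
    │     refcode, connectivity (1-based), n_atoms
    │     graph         list column: molgraph with cached ring info
    │     bits          list column: sorted 0-based set-bit indices
    │     elem_counts   list column: named integer element multiset
    │     max_assembly  largest ring-assembly size in atoms (0 = acyclic)
    ├── fingerprints     (refcode, connectivity, bits) view used by
    │                    similarity search; one row per connectivity
    ├── cells            one row per entry that has a cell
    │     refcode, a, b, c, alpha, beta, gamma          (as input)
    │     red_a .. red_gamma                            (Niggli reduced)
    │     niggli_type                                   ("I" or "II")
    └── text_postings    inverted index: field -> token -> posting list
          posting list: data.frame(refcode, pos) where pos is the 1-based
          token position within the field (drives phrase verification)
```

Invariants: one fingerprint row per connectivity; every posting references
an existing entry; indexed lookups return the same results as a full scan
(asserted by the test suite); rebuilding from the same inputs and schema
version is deterministic.

Derived artifacts (ring info, fingerprints, screens, reduced cells, token
postings) are all precomputed at build time; searches never recompute them.
`simsearch`/`subsearch` refuse settings that disagree with the `config`
recorded at build time (queries are compiled with the database's stored
fingerprint parameters).
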