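test_that("compile_query derives graphs and screens", {
  q <- compile_query("C=N")
  expect_equal(q$element, c("C", "N"))
  expect_equal(q$screens$elem_counts, c(C = 1L, N = 1L))
  expect_true(feature_bit("C=N") %in% q$screens$fp_bits)
  expect_equal(q$screens$max_assembly, 0L)

  q2 <- compile_query("Cl")
  expect_equal(q2$screens$elem_counts, c(Cl = 1L))

  q3 <- compile_query("C{ring:6-6}1CCCCC1")
  expect_equal(q3$ring_con[[1L]], list(type = "range", min = 6L, max = 6L))
  expect_equal(q3$screens$max_assembly, 6L)

  # wildcards and any-bonds contribute nothing to the feature screen
  q4 <- compile_query("*~C")
  expect_equal(q4$screens$elem_counts, c(C = 1L))
  expect_equal(q4$screens$fp_bits, feature_bit("C"))

  expect_error(compile_query("C{ring:8-4}C"), "min > max")
  expect_error(compile_query("C{ring:2-4}C"), ">= 3")
})

test_that("screens are sound and discriminating on the stated cases", {
  hexane_scr <- local({
    mol <- parse_linear("CCCCCC")
    list(elem_counts = c(C = 6L), fp_bits = fingerprint(mol)$bits,
         max_assembly = 0L)
  })
  expect_false(screen_pass(compile_query("Cl"), hexane_scr))
  expect_true(screen_pass(compile_query("CCCCCC"), hexane_scr))

  # macrocycle assembly screen: a 12-ring query cannot match smaller systems
  macro <- compile_query("C1CCCCCCCCCCC1")
  naph <- with_ring_info(parse_linear("C1=CC=C2C=CC=CC2=C1"))
  naph_scr <- list(elem_counts = c(C = 10L), fp_bits = fingerprint(naph)$bits,
                   max_assembly = compute_ring_info(naph)$max_assembly)
  expect_false(screen_pass(macro, naph_scr))
})

test_that("ring constraints select by smallest ring size", {
  q66 <- compile_query("C{ring:6-6}")
  expect_length(match_substructure(q66, parse_linear("C1CCCC1")), 0L)
  expect_length(match_substructure(q66, parse_linear("C1=CC=CC=C1")), 6L)
  # naphthalene bridgeheads are in 6-rings
  expect_length(match_substructure(q66, parse_linear("C1=CC=C2C=CC=CC2=C1")), 10L)

  qac <- compile_query("C{ring:acyclic}C{ring:3-6}")
  # methylcyclopentane: methyl is acyclic, ring atoms in a 5-ring
  mcp <- parse_linear("CC1CCCC1")
  maps <- match_substructure(qac, mcp)
  expect_true(length(maps) >= 1L)
  expect_true(all(vapply(maps, function(m) m[1L] == 1L, TRUE)))

  # bond-level ring constraint
  qb <- compile_query("C={ring:6-6}C")
  expect_length(match_substructure(qb, parse_linear("C1=CC=CC=C1")), 6L)
  expect_length(match_substructure(qb, parse_linear("C=C")), 0L)
})

test_that("matcher equals the exhaustive oracle on catalog x query pairs", {
  mols <- catalog_molecules()
  mols <- mols[vapply(mols, n_atoms, 0L) <= 12L]
  queries <- c("C=N", "Cl", "C-C=C", "C{ring:6-6}", "C{ring:acyclic}C",
               "*~C~*", "C1CCCCC1", "C1=CC=CC=C1", "O=C", "C{ring:5-6}1CCCC1",
               "*=O", "C~C~C~C")
  n_checked <- 0L
  for (qs in queries) {
    q <- compile_query(qs)
    for (nm in names(mols)) {
      got <- match_substructure(q, mols[[nm]], find_all = TRUE)
      want <- oracle_mappings(q, mols[[nm]])
      expect_identical(map_key(got), map_key(want),
                       info = sprintf("%s vs %s", qs, nm))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("matcher handles charges per the charge-matching contract", {
  mol <- parse_linear("C[N+](C)C")
  # plain atoms constrain charge to zero
  expect_length(match_substructure(compile_query("N"), mol), 0L)
  expect_length(match_substructure(compile_query("[N+]"), mol), 1L)
  expect_length(match_substructure(compile_query("N{charge:any}"), mol), 1L)
  expect_length(match_substructure(compile_query("*"), mol), 4L)
})

test_that("first-match mode stops early but agrees on existence", {
  mols <- catalog_molecules()
  q <- compile_query("C-C")
  one <- match_substructure(q, mols$hexane, find_all = FALSE)
  all_m <- match_substructure(q, mols$hexane, find_all = TRUE)
  expect_length(one, 1L)
  expect_equal(length(all_m), 10L)  # 5 bonds x 2 directions
})

test_that("screen soundness holds across seeded random query/molecule pairs", {
  spec <- fixture_spec(seed = 99, n_atoms_range = c(4L, 10L), charge_prob = 0.1)
  mols <- random_molecules(spec, 50)
  queries <- lapply(c("C", "N", "O", "C-C", "C=O", "C-N", "C~O", "*~N",
                      "[N+1]", "C{ring:acyclic}", "C{ring:3-8}", "C-C-C",
                      "[O-]", "S", "C=C", "N{charge:any}", "C(C)C", "C~C~C",
                      "Cl", "F"), compile_query)
  pairs <- 0L
  true_matches <- 0L
  for (mol in mols) {
    scr <- list(elem_counts = table_to_counts(mol),
                fp_bits = fingerprint(mol)$bits,
                max_assembly = compute_ring_info(mol)$max_assembly)
    for (q in queries) {
      pairs <- pairs + 1L
      hit <- length(match_substructure(q, mol, find_all = FALSE)) > 0L
      if (hit) {
        true_matches <- true_matches + 1L
        expect_true(screen_pass(q, scr))
      }
    }
  }
  expect_equal(pairs, 1000L)
  expect_gte(true_matches, 100L)  # the sweep must actually exercise matches
})

test_that("hit sets are identical with and without screens", {
  fixture <- fixture_db_cached()
  db <- fixture$db
  for (qs in c("C=N", "Cl", "C1=CC=CC=C1", "C{ring:6-6}", "*~O")) {
    with_scr <- substructure_search(qs, db, use_screens = TRUE)
    without <- substructure_search(qs, db, use_screens = FALSE)
    attr(with_scr, "counts") <- NULL
    attr(without, "counts") <- NULL
    expect_identical(with_scr, without, info = qs)
  }
})

test_that("substructure search returns manifest ground truth", {
  fixture <- fixture_db_cached()
  db <- fixture$db
  man <- fixture$fx$manifest
  hits <- substructure_search("C=N", db)
  expect_equal(sort(unique(hits$refcode)), sort(man$refcode[man$has_CN_double]))
  hits_cl <- substructure_search("Cl", db)
  expect_equal(sort(unique(hits_cl$refcode)), sort(man$refcode[man$has_Cl]))
  # query equal to a full stored connectivity finds its own entry
  hits_self <- substructure_search("C1=CC=C2C=CC=CC2=C1", db)
  expect_true("FIX010" %in% hits_self$refcode)
})

test_that("hit sets are invariant under atom relabeling of the targets", {
  set.seed(42)
  mols <- catalog_molecules()[c("pyridine", "naphthalene", "chlorobenzene")]
  for (qs in c("C=N", "Cl", "C{ring:6-6}")) {
    q <- compile_query(qs)
    for (mol in mols) {
      n1 <- length(match_substructure(q, mol))
      perm <- sample(n_atoms(mol))
      n2 <- length(match_substructure(q, permute_atoms(mol, perm)))
      expect_equal(n2, n1)
    }
  }
})
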