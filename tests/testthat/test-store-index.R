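test_that("tokenize lowercases, splits and preserves order", {
  expect_true("thiadiazine" %in% tokenize("5-amino-2H-1,2,6-thiadiazine-1,1-dioxide"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize(NA), character(0))
  expect_identical(tokenize("Needle; prism"), c("needle", "prism"))
  expect_identical(tokenize("A  b--c"), c("a", "b", "c"))
})

test_that("build_database precomputes one fingerprint row per connectivity", {
  fixture <- fixture_db_cached()
  db <- fixture$db
  expect_equal(nrow(db$tables$entries), 20L)
  expect_equal(nrow(db$tables$fingerprints), nrow(db$tables$connectivities))
  # the two-connectivity entry has two fingerprint rows linked to one entry
  expect_equal(sum(db$tables$fingerprints$refcode == "FIX009"), 2L)
  expect_equal(sum(db$tables$entries$refcode == "FIX009"), 1L)
  expect_error(
    build_database(list(entry_record("AAA"), entry_record("AAA"))),
    "duplicate refcode"
  )
  expect_warning(build_database(list(entry_record("EMPTY1"))), "metadata-only")
})

test_that("database round-trips through save/load with identical results", {
  fixture <- fixture_db_cached()
  db <- fixture$db
  path <- tempfile(fileext = ".xdb")
  save_database(db, path)
  db2 <- load_database(path)
  expect_equal(text_search(db2, "habit", "needle"), text_search(db, "habit", "needle"))
  expect_equal(substructure_search("C=N", db2)$refcode,
               substructure_search("C=N", db)$refcode)
  unlink(path)
})

test_that("rebuilding and insertion order do not change query results", {
  fixture <- fixture_db_cached()
  fx <- fixture$fx
  db1 <- fixture$db
  db2 <- build_database(fx$entries)
  expect_identical(db1$tables$fingerprints$bits, db2$tables$fingerprints$bits)
  db3 <- build_database(rev(fx$entries))
  expect_equal(text_search(db3, "habit", "needle"), text_search(db1, "habit", "needle"))
  expect_equal(run_composite(db3, list(fq_text("habit", "needle"))),
               run_composite(db1, list(fq_text("habit", "needle"))))
  expect_equal(substructure_search("Cl", db3)$refcode,
               substructure_search("Cl", db1)$refcode)
})

test_that("text queries equal a full linear scan", {
  fixture <- fixture_db_cached()
  db <- fixture$db
  fx <- fixture$fx
  cases <- list(
    c("habit", "needle"), c("habit", "plate"), c("bioactivity", "antibacterial"),
    c("compound_name", "thiadiazine"), c("all_text", "drug"),
    c("all_text", "agonist"),             # absent everywhere
    c("author", "author03"),
    c("compound_name", "benzene; cyclohexane")  # phrase
  )
  for (cs in cases) {
    expect_identical(text_search(db, cs[1L], cs[2L]),
                     oracle_text_scan(fx$entries, cs[1L], cs[2L]),
                     info = paste(cs, collapse = ":"))
  }
  expect_identical(text_search(db, "habit", "absenttoken"), character(0))
  expect_error(text_search(db, "bogus_field", "x"), "unknown text field")
})

test_that("phrase search verifies token positions", {
  entries <- list(
    entry_record("PHR001", compound_name = "alpha beta gamma"),
    entry_record("PHR002", compound_name = "beta alpha delta gamma"),
    entry_record("PHR003", compound_name = "alpha gamma")
  )
  db <- suppressWarnings(build_database(entries))
  expect_equal(text_search(db, "compound_name", "alpha beta"), "PHR001")
  expect_equal(text_search(db, "compound_name", "alpha gamma"), "PHR003")
  expect_setequal(text_search(db, "compound_name", "alpha"),
                  c("PHR001", "PHR002", "PHR003"))
})

test_that("composite queries intersect and honor dates and defined-ness", {
  fixture <- fixture_db_cached()
  db <- fixture$db
  man <- fixture$fx$manifest

  got <- run_composite(db, list(fq_text("habit", "needle"),
                                fq_defined("phase_transitions")))
  want <- sort(man$refcode[!is.na(man$habit) & man$habit == "needle" &
                           man$phase_transitions_defined])
  expect_identical(got, want)

  # single-item conjunction equals the bare query
  expect_identical(run_composite(db, list(fq_text("habit", "needle"))),
                   text_search(db, "habit", "needle"))

  # date-restricted bioactive plates: oracle by direct scan of the manifest
  cutoff <- "2006-01-01"
  got2 <- run_composite(db, list(fq_defined("bioactivity"),
                                 fq_date_range("date_added", lo = cutoff)))
  want2 <- sort(man$refcode[man$bioactive & man$date_added >= cutoff])
  expect_identical(got2, want2)

  # numeric range
  got3 <- run_composite(db, list(fq_numeric_range("year", 2005, 2006)))
  want3 <- sort(man$refcode[man$year >= 2005 & man$year <= 2006])
  expect_identical(got3, want3)

  # conjunction monotonicity: adding an item never grows the set
  base <- run_composite(db, list(fq_defined("bioactivity")))
  narrowed <- run_composite(db, list(fq_defined("bioactivity"),
                                     fq_text("habit", "needle")))
  expect_true(all(narrowed %in% base))

  expect_error(run_composite(db, list()), "empty conjunction")
})

test_that("adding newer entries is recoverable via a date filter", {
  fixture <- fixture_db_cached()
  fx <- fixture$fx
  newer <- entry_record("ZZZ001", connectivities = list(parse_linear("CCO")),
                        habit = "plate", bioactivity = "antiviral",
                        date_added = "2020-06-01")
  db2 <- build_database(c(fx$entries, list(newer)))
  got <- run_composite(db2, list(fq_defined("bioactivity"),
                                 fq_date_range("date_added", lo = "2020-01-01")))
  expect_identical(got, "ZZZ001")
})
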