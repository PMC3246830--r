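test_that("parse_linear builds the expected graphs", {
  hexane <- parse_linear("CCCCCC")
  expect_equal(n_atoms(hexane), 6L)
  expect_equal(n_bonds(hexane), 5L)
  expect_true(all(hexane$bonds$order == 1L))

  cyclohexane <- parse_linear("C1CCCCC1")
  expect_equal(n_atoms(cyclohexane), 6L)
  expect_equal(n_bonds(cyclohexane), 6L)

  benzene <- parse_linear("C1=CC=CC=C1")
  expect_equal(n_atoms(benzene), 6L)
  expect_equal(sum(benzene$bonds$order == 1L), 3L)
  expect_equal(sum(benzene$bonds$order == 2L), 3L)
  ri <- compute_ring_info(benzene)
  expect_equal(lengths(ri$rings), 6L)

  charged <- parse_linear("[N+](C)(C)C")
  expect_equal(charged$charge, c(1L, 0L, 0L, 0L))
  expect_equal(atom_degree(charged)[1L], 3L)
})

test_that("parse_linear reports errors with character offsets", {
  expect_error(parse_linear("C(C"), "unmatched")
  expect_error(parse_linear("C1CC"), "unclosed ring digit")
  expect_error(parse_linear("CxC"), "character 2")
  expect_error(parse_linear("C*C"), "queries")
  expect_error(parse_linear("C~C"), "queries")
  expect_error(parse_linear("[Xx]"), "unknown element")
})

test_that("SDF round-trip preserves atoms, bonds, orders and charges", {
  mols <- catalog_molecules()
  charged <- parse_linear("[N+](C)(C)CC(=O)[O-]", name = "betaine_like")
  for (mol in c(mols[c("benzene", "spiro45decane", "chlorobenzene")],
                list(charged))) {
    lines <- write_sdf(mol)
    back <- read_sdf(lines)
    expect_length(back, 1L)
    expect_length(back[[1L]]$connectivities, 1L)
    got <- back[[1L]]$connectivities[[1L]]
    expect_equal(got$element, mol$element)
    expect_equal(got$charge, mol$charge)
    expect_equal(got$bonds, mol$bonds)
  }
})

test_that("read_sdf handles multi-record, multi-component and property input", {
  benzene <- parse_linear("C1=CC=CC=C1", name = "benzene")
  hexane <- parse_linear("CCCCCC", name = "hexane")
  lines <- c(write_sdf(benzene, properties = list(list(ID = "one"))),
             write_sdf(hexane, properties = list(list(ID = "two"))))
  recs <- read_sdf(lines)
  expect_length(recs, 2L)
  expect_equal(recs[[1L]]$properties$ID, "one")
  expect_equal(recs[[2L]]$properties$ID, "two")

  # two components in one record share the property map
  two <- molgraph(c("C", "C", "O", "O"),
                  data.frame(a = c(1, 3), b = c(2, 4), order = c(1, 1)),
                  check_connected = FALSE)
  lines2 <- write_sdf(list(two), properties = list(list(SRC = "mix")))
  recs2 <- read_sdf(lines2)
  expect_length(recs2[[1L]]$connectivities, 2L)
  expect_equal(vapply(recs2[[1L]]$connectivities, n_atoms, 0L), c(2L, 2L))
  expect_equal(recs2[[1L]]$properties$SRC, "mix")

  expect_identical(read_sdf(character(0)), list())
})

test_that("read_sdf rejects malformed records with line numbers", {
  good <- write_sdf(parse_linear("CCCCCC"))
  bad <- good
  bond_line <- grep("^  1  2  1", bad)[1L]
  bad[bond_line] <- "  1  7  1  0"
  expect_error(read_sdf(bad), "atom 7 of 6")
  expect_error(read_sdf(bad), paste("line", bond_line))

  bad2 <- good
  bad2[grep("V2000", bad2)] <- "  x  5  0  0  0  0  0  0  0  0999 V2000"
  expect_error(read_sdf(bad2), "counts|atom count")

  bad3 <- good
  atom_line <- grep("^ *0\\.0000", bad3)[1L]
  bad3[atom_line] <- sub(" C ", " Qq", bad3[atom_line])
  expect_error(read_sdf(bad3), "unknown element")
})

test_that("read_cif_cell extracts the six parameters and strips uncertainties", {
  cif <- c("data_x",
           "_cell_length_a 5.0(1)", "_cell_length_b 5.00", "_cell_length_c 5.0",
           "_cell_angle_alpha 90", "_cell_angle_beta 90.0(2)", "_cell_angle_gamma 90")
  cell <- read_cif_cell(cif)
  expect_equal(unlist(cell[c("a", "b", "c", "alpha", "beta", "gamma")],
                      use.names = FALSE), c(5, 5, 5, 90, 90, 90))

  cif2 <- c("_cell_length_a 3.1", "_cell_length_b 4.2", "_cell_length_c 5.3",
            "_cell_angle_alpha 80", "_cell_angle_beta 85", "_cell_angle_gamma 95")
  cell2 <- read_cif_cell(cif2)
  expect_equal(c(cell2$a, cell2$b, cell2$c, cell2$alpha, cell2$beta, cell2$gamma),
               c(3.1, 4.2, 5.3, 80, 85, 95))

  expect_error(read_cif_cell(cif2[-5L]), "missing _cell_angle_beta")

  # round-trip through the writer
  back <- read_cif_cell(write_cif_cell(cell2))
  expect_equal(cell_params <- unlist(back[1:6]), unlist(cell2[1:6]), tolerance = 1e-9)
})

test_that("ring info matches brute-force shortest-cycle search", {
  cases <- list(
    hexane = parse_linear("CCCCCC"),
    naphthalene = parse_linear("C1=CC=C2C=CC=CC2=C1"),
    spiro = parse_linear("C1CCCC12CCCCC2"),
    phenylacetate = parse_linear("CC(=O)OC1=CC=CC=C1"),
    bicyclo = parse_linear("C1CC2CCC1CC2")
  )
  for (nm in names(cases)) {
    mol <- cases[[nm]]
    ri <- compute_ring_info(mol)
    expect_equal(length(ri$rings), n_bonds(mol) - n_atoms(mol) + 1L, info = nm)
    brute <- vapply(seq_len(n_atoms(mol)), function(v) {
      oracle_smallest_ring_atom(mol, v)
    }, NA_integer_)
    expect_equal(ri$atom_srs, brute, info = nm)
  }
})

test_that("ring assemblies group fused and spiro systems", {
  naph <- compute_ring_info(parse_linear("C1=CC=C2C=CC=CC2=C1"))
  expect_length(naph$assemblies, 1L)
  expect_equal(naph$assemblies[[1L]]$size, 10L)
  expect_true(all(naph$atom_srs == 6L))

  spiro <- compute_ring_info(parse_linear("C1CCCC12CCCCC2"))
  expect_length(spiro$assemblies, 1L)
  expect_equal(spiro$max_assembly, 10L)
  expect_equal(sort(lengths(spiro$rings)), c(5L, 6L))
  # the spiro atom (index 5) sits in both rings; its smallest is the 5-ring
  expect_equal(spiro$atom_srs[5L], 5L)

  biphenyl_like <- compute_ring_info(parse_linear("C1=CC=CC=C1C1=CC=CC=C1"))
  expect_length(biphenyl_like$assemblies, 2L)
  expect_equal(biphenyl_like$max_assembly, 6L)

  expect_length(compute_ring_info(parse_linear("CCCCCC"))$rings, 0L)
  expect_true(all(is.na(compute_ring_info(parse_linear("CCCCCC"))$atom_srs)))
})

test_that("ring info is invariant under atom relabeling (property)", {
  set.seed(11)
  mols <- random_molecules(fixture_spec(seed = 11, n_atoms_range = c(4L, 10L)), 15)
  for (mol in mols) {
    perm <- sample(n_atoms(mol))
    ri1 <- compute_ring_info(mol)
    ri2 <- compute_ring_info(permute_atoms(mol, perm))
    expect_equal(ri2$atom_srs[perm], ri1$atom_srs)
    expect_equal(sort(lengths(ri2$rings)), sort(lengths(ri1$rings)))
    expect_equal(ri2$max_assembly, ri1$max_assembly)
  }
})

test_that("hydrogen suppression removes H atoms and their bonds", {
  mol <- molgraph(c("C", "H", "H", "O"),
                  data.frame(a = c(1, 1, 1), b = c(2, 3, 4), order = 1L))
  sup <- suppress_hydrogens(mol)
  expect_equal(sup$element, c("C", "O"))
  expect_equal(n_bonds(sup), 1L)
})
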