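# Deterministic synthetic fixtures.
#
# Every search mode is testable without external data: a fixed molecule
# catalog carries the analytically known cases (cyclicity-blind fingerprint
# pairs, ring-size carriers, macrocycles, a drug-analog family sharing a
# benzimidazole-sulfinyl-pyridine scaffold plus unrelated decoys), and
# seeded generators produce random molecules, unit cells and complete
# database inputs with a ground-truth manifest.

CATALOG_NOTATION <- c(
  hexane = "CCCCCC",
  cyclohexane = "C1CCCCC1",
  benzene = "C1=CC=CC=C1",
  naphthalene = "C1=CC=C2C=CC=CC2=C1",
  spiro45decane = "C1CCCC12CCCCC2",
  chlorobenzene = "ClC1=CC=CC=C1",
  fluorobenzene = "FC1=CC=CC=C1",
  pyridine = "C1=CC=CC=N1",
  macrocycle12 = "C1CCCCCCCCCCC1",
  c20 = "CCCCCCCCCCCCCCCCCCCC",
  # simplified Kekule analogs of the anti-ulcerative benzimidazole family
  pantoprazole_analog = "C1=CC=C2N=C(NC2=C1)S(=O)CC3=CC=CC=N3",
  omeprazole_analog = "C1=CC(OC)=C2N=C(NC2=C1)S(=O)CC3=CC(C)=CC=N3",
  lansoprazole_analog = "FC1=CC=C2N=C(NC2=C1)S(=O)CC3=CC=CC=N3",
  # unrelated decoys
  decoy_ethanol = "CCO",
  decoy_phenylacetate = "CC(=O)OC1=CC=CC=C1",
  decoy_decane = "CCCCCCCCCC",
  decoy_cyclohexanone = "O=C1CCCCC1",
  decoy_guanidine = "CNC(=N)N"
)

#' Catalog of named fixture molecules
#'
#' @return Named list of `molgraph`s parsed from the bundled linear
#'   notations (Kekule forms, hydrogen suppressed).
#' @export
catalog_molecules <- function() {
  out <- lapply(names(CATALOG_NOTATION), function(nm) {
    parse_linear(CATALOG_NOTATION[[nm]], name = nm)
  })
  stats::setNames(out, names(CATALOG_NOTATION))
}

#' Fixture generation settings
#'
#' @param seed Integer seed; the same seed and spec give identical output.
#' @param n_entries Number of database entries (default 20).
#' @param n_atoms_range Atom-count range for random molecules.
#' @param ring_prob Probability of each of two candidate ring-closure edges
#'   being added to a random molecule's spanning tree.
#' @param elements Element alphabet for random molecules.
#' @param element_weights Sampling weights, same length as `elements`.
#' @param charge_prob Probability that an N/O atom carries a +/-1 charge.
#' @param length_range,angle_range Reduced-parameter ranges for random cells.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 20100212L, n_entries = 20L,
                         n_atoms_range = c(4L, 12L), ring_prob = 0.4,
                         elements = c("C", "N", "O", "S", "Cl", "F"),
                         element_weights = c(12, 3, 3, 1, 1, 1),
                         charge_prob = 0.05,
                         length_range = c(4, 15), angle_range = c(70, 115)) {
  stopifnot(n_entries >= 1L, n_atoms_range[1L] >= 1L,
            n_atoms_range[1L] <= n_atoms_range[2L],
            ring_prob >= 0, ring_prob <= 1,
            length_range[1L] > 0, length_range[1L] <= length_range[2L],
            angle_range[1L] > 0, angle_range[2L] < 180)
  structure(list(seed = as.integer(seed), n_entries = as.integer(n_entries),
                 n_atoms_range = as.integer(n_atoms_range),
                 ring_prob = ring_prob, elements = elements,
                 element_weights = element_weights, charge_prob = charge_prob,
                 length_range = length_range, angle_range = angle_range),
            class = "fixture_spec")
}

#' Seeded random molecules
#'
#' Random spanning tree plus up to two ring-closure edges (each added with
#' probability `ring_prob`), elements drawn from the alphabet, bond orders
#' mostly single. Sets the RNG seed from the spec; all outputs are
#' connected, valid `molgraph`s.
#'
#' @param spec A `fixture_spec`.
#' @param n Number of molecules.
#' @return List of `molgraph`s.
#' @export
random_molecules <- function(spec, n = spec$n_entries) {
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) random_molecule(spec, paste0("rand", i)))
}

random_molecule <- function(spec, name = "") {
  na <- sample(seq(spec$n_atoms_range[1L], spec$n_atoms_range[2L]), 1L)
  element <- sample(spec$elements, na, replace = TRUE, prob = spec$element_weights)
  charge <- integer(na)
  chargeable <- which(element %in% c("N", "O"))
  for (i in chargeable) {
    if (stats::runif(1) < spec$charge_prob) {
      charge[i] <- sample(c(-1L, 1L), 1L)
    }
  }
  sample_order <- function(k) sample(1:3, k, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  bonds <- empty_bonds()
  for (i in seq_len(na)[-1L]) {
    j <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1L)
    bonds <- rbind(bonds, data.frame(a = j, b = i, order = sample_order(1L)))
  }
  if (na >= 4L) {
    present <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    for (try in 1:2) {
      if (stats::runif(1) < spec$ring_prob) {
        pair <- sort(sample(na, 2L))
        key <- paste(pair[1L], pair[2L])
        if (!key %in% present) {
          bonds <- rbind(bonds, data.frame(a = pair[1L], b = pair[2L], order = 1L))
          present <- c(present, key)
        }
      }
    }
  }
  molgraph(element, bonds, charge, name = name)
}

#' Seeded random unit cells
#'
#' Cells are drawn directly in a near-reduced parameterization (sorted
#' lengths, angles in the given range) and rejected until the metric is
#' positive definite. With `scramble = TRUE` each cell is also returned in
#' a random unimodular basis, giving scrambled duplicates with known
#' ground-truth lattice identity.
#'
#' @param spec A `fixture_spec`.
#' @param n Number of cells.
#' @param scramble Also return scrambled-basis copies.
#' @return List of `unit_cell`s; when `scramble` is `TRUE`, a list with
#'   `cells`, `scrambled` and the `transforms` used.
#' @export
random_cells <- function(spec, n = spec$n_entries, scramble = FALSE) {
  set.seed(spec$seed + 1L)
  cells <- lapply(seq_len(n), function(i) random_cell(spec))
  if (!scramble) return(cells)
  transforms <- lapply(seq_len(n), function(i) random_unimodular())
  scrambled <- mapply(transform_cell, cells, transforms, SIMPLIFY = FALSE)
  list(cells = cells, scrambled = scrambled, transforms = transforms)
}

random_cell <- function(spec) {
  repeat {
    lens <- sort(stats::runif(3L, spec$length_range[1L], spec$length_range[2L]))
    angs <- stats::runif(3L, spec$angle_range[1L], spec$angle_range[2L])
    cell <- try(unit_cell(lens[1L], lens[2L], lens[3L],
                          angs[1L], angs[2L], angs[3L]), silent = TRUE)
    if (!inherits(cell, "try-error") && is.finite(cell_volume(cell))) return(cell)
  }
}

#' Random unimodular matrix
#'
#' Rejection-samples integer 3x3 matrices with entries in `-max_entry ..
#' max_entry` until the determinant is +/-1.
#'
#' @param max_entry Entry bound (default 2).
#' @return Integer matrix with `det = +/-1`.
#' @export
random_unimodular <- function(max_entry = 2L) {
  repeat {
    m <- matrix(sample(seq(-max_entry, max_entry), 9L, replace = TRUE), 3, 3)
    if (abs(abs(det(m)) - 1) < 0.5) {
      storage.mode(m) <- "integer"
      return(m)
    }
  }
}

# Default metadata vocabularies for the fixture database.
.HABITS <- c("needle", "plate", "prism", "block")

#' Generate fixture entry records with a ground-truth manifest
#'
#' Builds a complete, deterministic set of entry records: the drug-analog
#' family and decoys from the catalog, further catalog molecules (one entry
#' with two connectivities), random molecules, random cells including one
#' scrambled-basis lattice duplicate pair, one near-90-degree boundary
#' lattice, and one angle-decoy pair (equal reduced lengths, angles
#' differing well beyond tolerance). Exactly four entries have habit
#' "needle". The manifest records, per entry, the fields and identities the
#' search tests assert against.
#'
#' @param spec A `fixture_spec`.
#' @return List with `entries` (list of `entry_record`) and `manifest`
#'   (data frame).
#' @export
fixture_entries <- function(spec = fixture_spec()) {
  cat_mols <- catalog_molecules()
  n <- spec$n_entries
  refcodes <- sprintf("FIX%03d", seq_len(n))
  # molecule assignment: catalog first (analogs, decoys, carriers), then random
  assignment <- list(
    list(cat_mols$pantoprazole_analog),
    list(cat_mols$omeprazole_analog),
    list(cat_mols$lansoprazole_analog),
    list(cat_mols$decoy_ethanol),
    list(cat_mols$decoy_phenylacetate),
    list(cat_mols$decoy_decane),
    list(cat_mols$decoy_cyclohexanone),
    list(cat_mols$decoy_guanidine),
    list(cat_mols$benzene, cat_mols$cyclohexane),  # two connectivities
    list(cat_mols$naphthalene),
    list(cat_mols$pyridine),
    list(cat_mols$chlorobenzene),
    list(cat_mols$macrocycle12)
  )
  if (n > length(assignment)) {
    rnd <- random_molecules(spec, n - length(assignment))
    for (m in rnd) assignment[[length(assignment) + 1L]] <- list(m)
  }
  assignment <- assignment[seq_len(n)]

  # cells: random, with designated structure
  cellinfo <- random_cells(spec, n, scramble = FALSE)
  lattice_group <- seq_len(n)
  set.seed(spec$seed + 2L)
  if (n >= 2L) {
    # entry 2 carries entry 1's lattice in a scrambled basis
    cellinfo[[2L]] <- transform_cell(cellinfo[[1L]], random_unimodular())
    lattice_group[2L] <- 1L
  }
  if (n >= 4L) {
    # angle-decoy pair: equal reduced lengths, angles ~10 degrees apart
    cellinfo[[3L]] <- unit_cell(5, 6, 7, 80, 85, 88)
    cellinfo[[4L]] <- unit_cell(5, 6, 7, 70, 75, 78)
    lattice_group[3L] <- 3L
    lattice_group[4L] <- 4L
  }
  if (n >= 5L) {
    # near-90-degree boundary cell: reduced angles unstable
    cellinfo[[5L]] <- unit_cell(6, 7, 8, 89.9, 90, 90)
    lattice_group[5L] <- 5L
  }

  habits <- rep(NA_character_, n)
  needle_idx <- intersect(c(1L, 4L, 9L, 13L), seq_len(n))
  habits[needle_idx] <- "needle"
  others <- setdiff(seq_len(n), needle_idx)
  habits[others] <- c(rep(c("plate", "prism", "block", NA), length.out = length(others)))

  phase_idx <- intersect(c(1L, 5L, 9L, 12L, 17L), seq_len(n))
  bioactive_idx <- intersect(c(1L, 2L, 3L, 5L, 14L), seq_len(n))

  dates <- format(as.Date("2005-01-15") + ((seq_len(n) - 1L) * 97L) %% 1700L)
  years <- 2004L + (seq_len(n) %% 6L)

  compound_names <- vapply(assignment, function(ms) {
    paste(vapply(ms, function(m) m$name, ""), collapse = "; ")
  }, "")
  compound_names[1L] <- paste0(compound_names[1L],
                               "; 5-(benzimidazolyl)sulfinyl derivative")
  if (n >= 11L) {
    compound_names[11L] <- "2H-1,2,6-thiadiazine-1,1-dioxide analog; pyridine"
  }

  entries <- vector("list", n)
  for (i in seq_len(n)) {
    entries[[i]] <- entry_record(
      refcode = refcodes[i],
      connectivities = assignment[[i]],
      cell = cellinfo[[i]],
      authors = sprintf("Author%02d, A.; Coauthor%02d, B.", i, (i %% 5L) + 1L),
      journal = c("Acta Cryst. B", "Cryst. Growth Des.", "J. Chem. Cryst.")[(i %% 3L) + 1L],
      compound_name = compound_names[i],
      synonyms = if (i %in% bioactive_idx) "drug candidate" else NA,
      habit = habits[i],
      bioactivity = if (i %in% bioactive_idx) {
        if (i <= 3L) "anti-ulcerative" else "antibacterial"
      } else NA,
      phase_transitions = if (i %in% phase_idx) "transition at 180 K" else NA,
      polymorphism = if (i %% 7L == 0L) "two polymorphs known" else NA,
      year = years[i],
      volume = 40L + i,
      first_page = 100L + 17L * i,
      date_added = dates[i],
      date_modified = format(as.Date(dates[i]) + 30L)
    )
  }

  manifest <- data.frame(
    refcode = refcodes,
    molecules = vapply(assignment, function(ms) {
      paste(vapply(ms, function(m) m$name, ""), collapse = ",")
    }, ""),
    n_connectivities = lengths(assignment),
    habit = habits,
    bioactive = seq_len(n) %in% bioactive_idx,
    phase_transitions_defined = seq_len(n) %in% phase_idx,
    date_added = dates,
    year = years,
    lattice_group = lattice_group
  )
  # ground-truth substructure labels for a few standing queries
  std_queries <- c(has_CN_double = "C=N", has_Cl = "Cl",
                   has_benzene = "C1=CC=CC=C1")
  for (qn in names(std_queries)) {
    q <- compile_query(std_queries[[qn]])
    manifest[[qn]] <- vapply(assignment, function(ms) {
      any(vapply(ms, function(m) {
        mh <- suppress_hydrogens(m)
        length(match_substructure(q, mh, find_all = FALSE)) > 0L
      }, TRUE))
    }, TRUE)
  }
  list(entries = entries, manifest = manifest)
}

#' Write a complete fixture database input to disk
#'
#' Produces the on-disk build inputs: one SDF and one CIF per entry, an
#' `entries.tsv` metadata table referencing them, and `manifest.tsv` with
#' the ground truth used by the search tests.
#'
#' @param spec A `fixture_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list from [fixture_entries()] plus `dir`.
#' @export
build_fixture_db <- function(spec = fixture_spec(), out_dir) {
  fx <- fixture_entries(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (e in fx$entries) {
    sdf_path <- file.path(out_dir, paste0(e$refcode, ".sdf"))
    cif_path <- file.path(out_dir, paste0(e$refcode, ".cif"))
    write_sdf(e$connectivities, sdf_path)
    sdf_rel <- basename(sdf_path)
    cif_rel <- ""
    if (!is.null(e$cell)) {
      write_cif_cell(e$cell, cif_path, data_name = e$refcode)
      cif_rel <- basename(cif_path)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      refcode = e$refcode, sdf = sdf_rel, cif = cif_rel,
      authors = e$authors, journal = e$journal,
      compound_name = e$compound_name, synonyms = e$synonyms,
      habit = e$habit, bioactivity = e$bioactivity,
      phase_transitions = e$phase_transitions, polymorphism = e$polymorphism,
      year = e$year, volume = e$volume, first_page = e$first_page,
      date_added = e$date_added, date_modified = e$date_modified,
      stringsAsFactors = FALSE
    )
  }
  entries_tsv <- do.call(rbind, rows)
  utils::write.table(entries_tsv, file.path(out_dir, "entries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(fx$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(c(fx, list(dir = out_dir)))
}

#' Read entry records from an entries TSV plus SDF/CIF files
#'
#' Inverse of [build_fixture_db()]: reads the tab-separated metadata table
#' (header row required; `sdf`/`cif` columns are paths relative to the TSV)
#' and assembles `entry_record`s.
#'
#' @param tsv_path Path to `entries.tsv`.
#' @return List of `entry_record`s.
#' @export
read_entries_tsv <- function(tsv_path) {
  base <- dirname(tsv_path)
  tab <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = "", comment.char = "")
  entries <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    conns <- list()
    if (!is.na(tab$sdf[i]) && nzchar(tab$sdf[i])) {
      recs <- read_sdf(file.path(base, tab$sdf[i]))
      for (rec in recs) conns <- c(conns, rec$connectivities)
    }
    cell <- NULL
    if (!is.na(tab$cif[i]) && nzchar(tab$cif[i])) {
      cell <- read_cif_cell(file.path(base, tab$cif[i]))
    }
    entries[[i]] <- entry_record(
      refcode = tab$refcode[i], connectivities = conns, cell = cell,
      authors = tab$authors[i], journal = tab$journal[i],
      compound_name = tab$compound_name[i], synonyms = tab$synonyms[i],
      habit = tab$habit[i], bioactivity = tab$bioactivity[i],
      phase_transitions = tab$phase_transitions[i],
      polymorphism = tab$polymorphism[i],
      year = tab$year[i], volume = tab$volume[i],
      first_page = tab$first_page[i],
      date_added = tab$date_added[i], date_modified = tab$date_modified[i]
    )
  }
  entries
}
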