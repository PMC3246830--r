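# Embedded relational store.
#
# A database is a single file holding a fixed, documented set of relational
# tables (see docs/SCHEMA.md): entry metadata, serialized connectivities,
# per-connectivity fingerprints and screens, raw + reduced cells, and a
# tokenized inverted text index with positional postings. Everything
# derived (fingerprints, ring info, screens, reduced cells, postings) is
# precomputed at build time so that searches only read the store. The file
# is written with R's native serialization; the schema, not the container,
# is the contract, and rebuilding from the same inputs is deterministic.

SCHEMA_VERSION <- 1L

TEXT_FIELDS <- c(author = "authors", journal = "journal",
                 compound_name = "compound_name", synonyms = "synonyms",
                 habit = "habit", bioactivity = "bioactivity",
                 phase_transitions = "phase_transitions",
                 polymorphism = "polymorphism")
NUMERIC_FIELDS <- c("year", "volume", "first_page")
DATE_FIELDS <- c("date_added", "date_modified")

#' Create an entry record
#'
#' One database entry: a refcode, zero or more connectivities, an optional
#' unit cell, and text/numeric/date metadata fields.
#'
#' @param refcode Non-empty uppercase identifier, unique within a database.
#' @param connectivities List of `molgraph`s (possibly empty).
#' @param cell A `unit_cell` or `NULL`.
#' @param authors,journal,compound_name,synonyms,habit,bioactivity,phase_transitions,polymorphism
#'   Text fields (string or `NA`).
#' @param year,volume,first_page Integers or `NA`.
#' @param date_added,date_modified ISO-8601 date strings or `NA`.
#' @return A list of class `entry_record`.
#' @export
entry_record <- function(refcode, connectivities = list(), cell = NULL,
                         authors = NA, journal = NA, compound_name = NA,
                         synonyms = NA, habit = NA, bioactivity = NA,
                         phase_transitions = NA, polymorphism = NA,
                         year = NA, volume = NA, first_page = NA,
                         date_added = NA, date_modified = NA) {
  refcode <- toupper(as.character(refcode))
  if (!nzchar(refcode) || is.na(refcode)) stop("refcode must be non-empty")
  for (d in c(date_added, date_modified)) {
    if (!is.na(d) && !grepl("^\\d{4}-\\d{2}-\\d{2}$", d)) {
      stop("dates must be ISO-8601 (YYYY-MM-DD): ", d)
    }
  }
  structure(list(
    refcode = refcode, connectivities = connectivities, cell = cell,
    authors = as.character(authors), journal = as.character(journal),
    compound_name = as.character(compound_name), synonyms = as.character(synonyms),
    habit = as.character(habit), bioactivity = as.character(bioactivity),
    phase_transitions = as.character(phase_transitions),
    polymorphism = as.character(polymorphism),
    year = as.integer(year), volume = as.integer(volume),
    first_page = as.integer(first_page),
    date_added = as.character(date_added), date_modified = as.character(date_modified)
  ), class = "entry_record")
}

#' Tokenize a text field
#'
#' Lowercases and splits on any non-alphanumeric character; empty tokens are
#' dropped and order is preserved (token positions drive phrase queries).
#' Hyphenated chemical names therefore yield their searchable fragments:
#' "1,2,6-thiadiazine" contains the token "thiadiazine".
#'
#' @param text A string (`NA` gives an empty token list).
#' @return Character vector of tokens.
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

#' Build a searchable database from entry records
#'
#' Precomputes, per connectivity: hydrogen-suppressed graph with ring info,
#' the 2040-bit fingerprint, and the screens used by substructure search
#' (element multiset, fingerprint bits, largest ring-assembly size); per
#' cell: the Niggli-reduced parameters; per text field: positional token
#' postings. The result is deterministic given the same entries and schema
#' version.
#'
#' @param entries List of `entry_record`s with unique refcodes.
#' @param out_path Optional path; when given, the database is also written
#'   there with [save_database()].
#' @param config Optional list overriding `fp_width` (2040),
#'   `max_path_atoms` (10), `rel_length` (0.01), `abs_angle` (1.0).
#' @param retain_h Keep explicit hydrogens instead of suppressing them.
#' @return An object of class `xtal_db`.
#' @export
build_database <- function(entries, out_path = NULL, config = list(),
                           retain_h = FALSE) {
  cfg <- utils::modifyList(list(fp_width = FP_WIDTH,
                                max_path_atoms = FP_MAX_PATH_ATOMS,
                                rel_length = 0.01, abs_angle = 1.0), config)
  refcodes <- vapply(entries, `[[`, "", "refcode")
  dup <- refcodes[duplicated(refcodes)]
  if (length(dup)) stop("duplicate refcode: ", dup[1L], call. = FALSE)
  ord <- order(refcodes)
  entries <- entries[ord]
  refcodes <- refcodes[ord]

  meta <- do.call(rbind, lapply(entries, function(e) {
    data.frame(refcode = e$refcode, authors = e$authors, journal = e$journal,
               compound_name = e$compound_name, synonyms = e$synonyms,
               habit = e$habit, bioactivity = e$bioactivity,
               phase_transitions = e$phase_transitions,
               polymorphism = e$polymorphism, year = e$year,
               volume = e$volume, first_page = e$first_page,
               date_added = e$date_added, date_modified = e$date_modified,
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL

  conn_rows <- list()
  cell_rows <- list()
  for (e in entries) {
    if (!length(e$connectivities) && is.null(e$cell)) {
      warning("entry ", e$refcode, " has neither molecule nor cell; stored metadata-only")
    }
    ci <- 0L
    for (mol in e$connectivities) {
      prepared <- if (retain_h) mol else suppress_hydrogens(mol)
      if (n_atoms(prepared) == 0L) next
      # hydrogen suppression can split a graph if H bridged two heavy atoms;
      # in a simple-graph model it cannot, but split defensively
      parts <- if (length(graph_components(n_atoms(prepared), prepared$bonds)$sizes) > 1L) {
        split_connectivities(prepared$element, prepared$bonds, prepared$charge, prepared$name)
      } else list(prepared)
      for (p in parts) {
        ci <- ci + 1L
        p <- with_ring_info(p)
        ri <- ring_info(p)
        fp <- fingerprint(p, width = cfg$fp_width, max_atoms = cfg$max_path_atoms)
        conn_rows[[length(conn_rows) + 1L]] <- list(
          refcode = e$refcode, connectivity = ci, n_atoms = n_atoms(p),
          graph = p, bits = fp$bits, elem_counts = element_counts(p),
          max_assembly = ri$max_assembly
        )
      }
    }
    if (!is.null(e$cell)) {
      red <- niggli_reduce(e$cell)
      rp <- cell_params(red$cell)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        refcode = e$refcode,
        a = e$cell$a, b = e$cell$b, c = e$cell$c,
        alpha = e$cell$alpha, beta = e$cell$beta, gamma = e$cell$gamma,
        red_a = rp[1], red_b = rp[2], red_c = rp[3],
        red_alpha = rp[4], red_beta = rp[5], red_gamma = rp[6],
        niggli_type = red$niggli_type
      )
    }
  }
  connectivities <- if (length(conn_rows)) {
    data.frame(
      refcode = vapply(conn_rows, `[[`, "", "refcode"),
      connectivity = vapply(conn_rows, `[[`, 0L, "connectivity"),
      n_atoms = vapply(conn_rows, `[[`, 0L, "n_atoms")
    )
  } else {
    data.frame(refcode = character(0), connectivity = integer(0), n_atoms = integer(0))
  }
  connectivities$graph <- lapply(conn_rows, `[[`, "graph")
  connectivities$bits <- lapply(conn_rows, `[[`, "bits")
  connectivities$elem_counts <- lapply(conn_rows, `[[`, "elem_counts")
  connectivities$max_assembly <- vapply(conn_rows, `[[`, 0L, "max_assembly")

  fingerprints <- connectivities[, c("refcode", "connectivity"), drop = FALSE]
  fingerprints$bits <- connectivities$bits

  cells <- if (length(cell_rows)) do.call(rbind, cell_rows) else NULL
  postings <- build_postings(meta)

  db <- structure(list(
    schema_version = SCHEMA_VERSION,
    config = cfg,
    tables = list(entries = meta, connectivities = connectivities,
                  fingerprints = fingerprints, cells = cells,
                  text_postings = postings)
  ), class = "xtal_db")
  if (!is.null(out_path)) save_database(db, out_path)
  db
}

build_postings <- function(meta) {
  postings <- list()
  for (qf in names(TEXT_FIELDS)) {
    col <- TEXT_FIELDS[[qf]]
    field_post <- list()
    for (r in seq_len(nrow(meta))) {
      toks <- tokenize(meta[[col]][r])
      for (p in seq_along(toks)) {
        tk <- toks[p]
        field_post[[tk]] <- rbind(field_post[[tk]],
                                  data.frame(refcode = meta$refcode[r], pos = p))
      }
    }
    postings[[qf]] <- field_post
  }
  postings
}

#' @export
print.xtal_db <- function(x, ...) {
  cat(sprintf("<xtal_db schema v%d: %d entries, %d connectivities, %d cells>\n",
              x$schema_version, nrow(x$tables$entries),
              nrow(x$tables$connectivities),
              if (is.null(x$tables$cells)) 0L else nrow(x$tables$cells)))
  invisible(x)
}

#' Save / load a database file
#'
#' @param db An `xtal_db`.
#' @param path File path (conventional extension `.xdb`).
#' @return `save_database` returns `path` invisibly; `load_database` the
#'   `xtal_db`.
#' @export
save_database <- function(db, path) {
  saveRDS(db, path, version = 3L)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path, call. = FALSE)
  db <- readRDS(path)
  if (!inherits(db, "xtal_db")) stop("not an xtalsearch database file", call. = FALSE)
  if (db$schema_version != SCHEMA_VERSION) {
    stop("schema version mismatch: file v", db$schema_version,
         ", package v", SCHEMA_VERSION, call. = FALSE)
  }
  db
}

#' Token or phrase search over the text index
#'
#' Single tokens are resolved from posting lists; a multi-token term is
#' treated as a phrase and verified against token positions. `all_text`
#' searches the union of all indexed text fields.
#'
#' @param db An `xtal_db`.
#' @param field One of `all_text`, `author`, `journal`, `compound_name`,
#'   `synonyms`, `habit`, `bioactivity`, `phase_transitions`, `polymorphism`.
#' @param term Token or phrase (whitespace/punctuation separate tokens).
#' @return Sorted character vector of matching refcodes.
#' @export
text_search <- function(db, field, term) {
  fields <- if (identical(field, "all_text")) names(TEXT_FIELDS) else field
  if (!all(fields %in% names(TEXT_FIELDS))) {
    stop("unknown text field: ", field, call. = FALSE)
  }
  toks <- tokenize(term)
  if (!length(toks)) return(character(0))
  hits <- character(0)
  for (f in fields) {
    fp <- db$tables$text_postings[[f]]
    if (length(toks) == 1L) {
      pl <- fp[[toks]]
      if (!is.null(pl)) hits <- c(hits, pl$refcode)
    } else {
      first <- fp[[toks[1L]]]
      if (is.null(first)) next
      for (r in unique(first$refcode)) {
        starts <- first$pos[first$refcode == r]
        ok <- any(vapply(starts, function(s) {
          all(vapply(seq_along(toks)[-1L], function(k) {
            pl <- fp[[toks[k]]]
            !is.null(pl) && any(pl$refcode == r & pl$pos == s + k - 1L)
          }, TRUE))
        }, TRUE))
        if (ok) hits <- c(hits, r)
      }
    }
  }
  sort(unique(hits))
}

#' Field query constructors
#'
#' A field query is one predicate over one schema field; composite queries
#' are conjunctions of field queries.
#'
#' @param field Field name (validated against the schema).
#' @param term Token or phrase for text fields.
#' @return A `field_query` object.
#' @export
fq_text <- function(field, term) {
  stopifnot(field %in% c("all_text", names(TEXT_FIELDS)))
  structure(list(kind = "text", field = field, term = term), class = "field_query")
}

#' @rdname fq_text
#' @param lo,hi Inclusive bounds; `NA` leaves the side open.
#' @export
fq_numeric_range <- function(field, lo = NA, hi = NA) {
  stopifnot(field %in% NUMERIC_FIELDS)
  structure(list(kind = "numeric", field = field, lo = lo, hi = hi),
            class = "field_query")
}

#' @rdname fq_text
#' @export
fq_date_range <- function(field, lo = NA, hi = NA) {
  stopifnot(field %in% DATE_FIELDS)
  structure(list(kind = "date", field = field, lo = lo, hi = hi),
            class = "field_query")
}

#' @rdname fq_text
#' @export
fq_defined <- function(field) {
  stopifnot(field %in% c(names(TEXT_FIELDS), NUMERIC_FIELDS, DATE_FIELDS))
  structure(list(kind = "defined", field = field), class = "field_query")
}

eval_field_query <- function(db, q) {
  meta <- db$tables$entries
  if (q$kind == "text") {
    return(text_search(db, q$field, q$term))
  }
  col <- if (q$field %in% names(TEXT_FIELDS)) TEXT_FIELDS[[q$field]] else q$field
  vals <- meta[[col]]
  if (q$kind == "defined") {
    keep <- !is.na(vals) & (!is.character(vals) | nzchar(trimws(as.character(vals))))
  } else if (q$kind == "numeric") {
    keep <- !is.na(vals) &
      (is.na(q$lo) | vals >= q$lo) & (is.na(q$hi) | vals <= q$hi)
  } else {  # date: ISO strings compare lexicographically
    keep <- !is.na(vals) &
      (is.na(q$lo) | vals >= q$lo) & (is.na(q$hi) | vals <= q$hi)
  }
  keep[is.na(keep)] <- FALSE
  sort(meta$refcode[keep])
}

#' Run a composite (AND) query
#'
#' @param db An `xtal_db`.
#' @param queries Non-empty list of `field_query` items; the result is the
#'   intersection of the per-item result sets.
#' @return Sorted character vector of refcodes.
#' @export
run_composite <- function(db, queries) {
  if (!length(queries)) stop("empty conjunction", call. = FALSE)
  res <- NULL
  for (q in queries) {
    hits <- eval_field_query(db, q)
    res <- if (is.null(res)) hits else intersect(res, hits)
  }
  sort(res)
}
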