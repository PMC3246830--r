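# V2000 SDF/MOL reading and writing.
#
# Only the connection table is used: coordinates are read past and ignored
# (2D connectivity searching only). Formal charges are taken from "M  CHG"
# property lines; the deprecated atom-block charge column is ignored.
# Explicit hydrogens are retained as read; callers that want the package's
# hydrogen-suppressed model apply suppress_hydrogens() afterwards.

sdf_error <- function(msg, line) {
  stop(sprintf("SDF parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read molecules from an SDF/MOL stream
#'
#' @param input A file path, a connection, or a character vector of lines.
#' @return A list with one element per `$$$$`-delimited record, each a list
#'   with fields `connectivities` (list of connected `molgraph`s -- a
#'   multi-component record is split, all components sharing the record's
#'   property map), `properties` (named list from the data items), and
#'   `name` (the title line).
#' @export
read_sdf <- function(input) {
  lines <- read_input_lines(input)
  out <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    # skip trailing blank lines between records
    if (all(!nzchar(trimws(lines[pos:length(lines)])))) break
    rec <- parse_sdf_record(lines, pos)
    out[[length(out) + 1L]] <- rec$record
    pos <- rec$next_pos
  }
  out
}

read_input_lines <- function(input) {
  if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else if (is.character(input) && length(input) == 1L && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (is.character(input)) {
    parts <- strsplit(input, "\n", fixed = TRUE)
    parts[lengths(parts) == 0L] <- list("")  # strsplit("") drops empty lines
    unlist(parts, use.names = FALSE)
  } else {
    stop("input must be a path, connection or character vector")
  }
}

fixed_int <- function(line, from, to, what, lineno) {
  s <- trimws(substr(line, from, to))
  if (!grepl("^-?[0-9]+$", s)) sdf_error(sprintf("malformed %s field", what), lineno)
  as.integer(s)
}

parse_sdf_record <- function(lines, pos) {
  name <- if (pos <= length(lines)) trimws(lines[pos]) else ""
  counts_line_no <- pos + 3L
  if (counts_line_no > length(lines)) sdf_error("truncated record header", length(lines))
  counts <- lines[counts_line_no]
  if (nchar(counts) < 6L) sdf_error("malformed counts line", counts_line_no)
  natoms <- fixed_int(counts, 1L, 3L, "atom count", counts_line_no)
  nbonds <- fixed_int(counts, 4L, 6L, "bond count", counts_line_no)
  if (natoms < 0L || nbonds < 0L) sdf_error("negative counts", counts_line_no)
  atom_start <- counts_line_no + 1L
  bond_start <- atom_start + natoms
  if (bond_start + nbonds - 1L > length(lines)) {
    sdf_error("truncated atom/bond block", length(lines))
  }
  element <- character(natoms)
  for (i in seq_len(natoms)) {
    ln <- atom_start + i - 1L
    fields <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(fields) < 4L) sdf_error("malformed atom line", ln)
    sym <- fields[4L]
    if (!is_element(sym)) sdf_error(sprintf("unknown element symbol '%s'", sym), ln)
    element[i] <- sym
  }
  bonds <- empty_bonds()
  for (i in seq_len(nbonds)) {
    ln <- bond_start + i - 1L
    line <- lines[ln]
    if (nchar(line) < 9L) sdf_error("malformed bond line", ln)
    a <- fixed_int(line, 1L, 3L, "bond atom", ln)
    b <- fixed_int(line, 4L, 6L, "bond atom", ln)
    ord <- fixed_int(line, 7L, 9L, "bond order", ln)
    if (a < 1L || a > natoms || b < 1L || b > natoms) {
      sdf_error(sprintf("bond references atom %d of %d", max(a, b), natoms), ln)
    }
    if (!ord %in% 1:3) sdf_error(sprintf("unsupported bond order %d", ord), ln)
    bonds <- rbind(bonds, data.frame(a = a, b = b, order = ord))
  }
  charge <- integer(natoms)
  pos <- bond_start + nbonds
  # property block until M  END
  while (pos <= length(lines)) {
    line <- lines[pos]
    if (grepl("^M  END", line)) { pos <- pos + 1L; break }
    if (grepl("^M  CHG", line)) {
      fields <- strsplit(trimws(sub("^M  CHG", "", line)), "[[:space:]]+")[[1L]]
      npairs <- as.integer(fields[1L])
      if (is.na(npairs) || length(fields) < 1L + 2L * npairs) {
        sdf_error("malformed M CHG line", pos)
      }
      for (p in seq_len(npairs)) {
        ai <- as.integer(fields[2L * p])
        cv <- as.integer(fields[2L * p + 1L])
        if (is.na(ai) || ai < 1L || ai > natoms) sdf_error("M CHG atom out of range", pos)
        charge[ai] <- cv
      }
    }
    pos <- pos + 1L
  }
  # data items until $$$$
  properties <- list()
  while (pos <= length(lines)) {
    line <- lines[pos]
    if (grepl("^\\$\\$\\$\\$", line)) { pos <- pos + 1L; break }
    m <- regmatches(line, regexec("^>\\s*<([^>]+)>", line))[[1L]]
    if (length(m)) {
      key <- m[2L]
      vals <- character(0)
      pos <- pos + 1L
      while (pos <= length(lines) && nzchar(trimws(lines[pos])) &&
             !grepl("^\\$\\$\\$\\$", lines[pos]) && !grepl("^>", lines[pos])) {
        vals <- c(vals, lines[pos])
        pos <- pos + 1L
      }
      properties[[key]] <- paste(vals, collapse = "\n")
    } else {
      pos <- pos + 1L
    }
  }
  conns <- split_connectivities(element, bonds, charge, name)
  list(record = list(connectivities = conns, properties = properties, name = name),
       next_pos = pos)
}

#' Write molecules as a V2000 SDF file
#'
#' Writes zero coordinates (the model is 2D connectivity only) and encodes
#' nonzero formal charges as `M  CHG` lines. Intended for fixture
#' generation and round-trip testing.
#'
#' @param mols A `molgraph` or list of `molgraph`s (each becomes one record).
#' @param path Output file path; if `NULL`, the lines are returned invisibly
#'   instead of written.
#' @param properties Optional list of named lists, one per molecule, written
#'   as SDF data items.
#' @return Invisibly, the character vector of lines written.
#' @export
write_sdf <- function(mols, path = NULL, properties = NULL) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  lines <- character(0)
  for (mi in seq_along(mols)) {
    mol <- mols[[mi]]
    lines <- c(lines, mol$name, "  xtalsearch", "")
    lines <- c(lines, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              n_atoms(mol), n_bonds(mol)))
    for (i in seq_len(n_atoms(mol))) {
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                0, 0, 0, mol$element[i]))
    }
    bd <- mol$bonds
    for (k in seq_len(nrow(bd))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", bd$a[k], bd$b[k], bd$order[k]))
    }
    charged <- which(mol$charge != 0L)
    while (length(charged)) {
      batch <- charged[seq_len(min(8L, length(charged)))]
      charged <- charged[-seq_len(min(8L, length(charged)))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(batch)),
                               paste0(sprintf("%4d%4d", batch, mol$charge[batch]),
                                      collapse = "")))
    }
    lines <- c(lines, "M  END")
    props <- if (!is.null(properties) && mi <= length(properties)) properties[[mi]] else NULL
    for (key in names(props)) {
      lines <- c(lines, sprintf("> <%s>", key), as.character(props[[key]]), "")
    }
    lines <- c(lines, "$$$$")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
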