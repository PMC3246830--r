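# Linear molecular notation.
#
# A deliberately small SMILES-like subset used for fixtures, queries and the
# CLI: organic-subset shorthand (B C N O P S F Cl Br I), bracket atoms with
# an optional charge ([N+], [O-2], [Fe]), bond symbols - = #, branches in
# parentheses, ring-closure digits 1-9. No aromatic lowercase, no stereo,
# no isotopes; implicit hydrogens are never added (hydrogen-suppressed
# model throughout).
#
# Query extensions (accepted only by compile_query): "*" wildcard atoms,
# "~" any-order bonds, and {...} annotations attaching to the preceding
# atom or bond: {ring:MIN-MAX}, {ring:MIN-}, {ring:-MAX}, {ring:acyclic},
# {charge:+N|-N|0|any}.

ORGANIC_TWO <- c("Cl", "Br")
ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")

lin_error <- function(msg, pos) {
  stop(sprintf("linear notation parse error at character %d: %s", pos, msg),
       call. = FALSE)
}

no_ring_constraint <- function() list(type = "none", min = NA_integer_, max = NA_integer_)

# Core tokenizer/builder. Returns a raw graph description; query-only tokens
# are rejected unless `query` is TRUE.
parse_linear_raw <- function(notation, query = FALSE) {
  chars <- strsplit(notation, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  atoms <- list()     # each: element, charge (NA = unconstrained), ring
  bonds <- list()     # each: a, b, order (NA = any), ring
  prev <- NA_integer_
  stack <- integer(0)
  pending_order <- NULL          # NULL = unspecified (single); NA = any (~)
  last_was_bond_symbol <- FALSE
  last_bond_idx <- NA_integer_
  ring_open <- list()            # digit -> list(atom, order, pos)
  i <- 1L

  add_atom <- function(element, charge, pos) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, charge = charge, ring = no_ring_constraint()
    )
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (is.null(pending_order)) 1L else pending_order
      bonds[[length(bonds) + 1L]] <<- list(
        a = prev, b = idx, order = ord, ring = no_ring_constraint()
      )
      last_bond_idx <<- length(bonds)
    }
    pending_order <<- NULL
    last_was_bond_symbol <<- FALSE
    prev <<- idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) lin_error("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) lin_error("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "~")) {
      if (ch == "~" && !query) lin_error("'~' bond allowed only in queries", i)
      pending_order <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, "~" = NA_integer_)
      last_was_bond_symbol <- TRUE
      i <- i + 1L
    } else if (grepl("[1-9]", ch)) {
      if (is.na(prev)) lin_error("ring digit before any atom", i)
      d <- ch
      spec <- if (is.null(pending_order)) NA_integer_ else pending_order
      spec_given <- !is.null(pending_order)
      if (is.null(ring_open[[d]])) {
        ring_open[[d]] <- list(atom = prev, order = spec, given = spec_given, pos = i)
      } else {
        op <- ring_open[[d]]
        if (op$atom == prev) lin_error("ring digit closes onto the same atom", i)
        ord <- if (spec_given && op$given) {
          if (!identical(spec, op$order)) lin_error("conflicting ring-closure bond orders", i)
          spec
        } else if (spec_given) spec else if (op$given) op$order else 1L
        bonds[[length(bonds) + 1L]] <- list(
          a = op$atom, b = prev, order = ord, ring = no_ring_constraint()
        )
        last_bond_idx <- length(bonds)
        ring_open[[d]] <- NULL
      }
      pending_order <- NULL
      last_was_bond_symbol <- FALSE
      i <- i + 1L
    } else if (ch == "[") {
      close <- NA_integer_
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == "]") { close <- j; break }
      }
      if (is.na(close)) lin_error("unmatched '['", i)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec("^([A-Z][a-z]?)([+-]?)([0-9]*)$", body))[[1L]]
      if (length(m) == 0L) lin_error(sprintf("bad bracket atom '[%s]'", body), i)
      elem <- m[2L]
      if (!is_element(elem)) lin_error(sprintf("unknown element '%s'", elem), i)
      charge <- 0L
      if (nzchar(m[3L])) {
        mag <- if (nzchar(m[4L])) as.integer(m[4L]) else 1L
        charge <- if (m[3L] == "+") mag else -mag
      } else if (nzchar(m[4L])) {
        lin_error("charge magnitude without sign", i)
      }
      add_atom(elem, charge, i)
      i <- close + 1L
    } else if (ch == "*") {
      if (!query) lin_error("'*' wildcard allowed only in queries", i)
      add_atom("*", NA_integer_, i)
      i <- i + 1L
    } else if (ch == "{") {
      if (!query) lin_error("'{...}' annotations allowed only in queries", i)
      close <- NA_integer_
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == "}") { close <- j; break }
      }
      if (is.na(close)) lin_error("unmatched '{'", i)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      ann <- parse_annotation(body, i)
      if (last_was_bond_symbol) {
        if (ann$kind != "ring") lin_error("only ring annotations apply to bonds", i)
        # stash on the pending bond: applied when the bond is materialized
        attr(pending_order, "ring") <- ann$ring
      } else {
        if (is.na(prev)) lin_error("annotation before any atom", i)
        if (ann$kind == "ring") {
          atoms[[prev]]$ring <- ann$ring
        } else {
          atoms[[prev]]$charge <- ann$charge
        }
      }
      i <- close + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% ORGANIC_TWO) {
        add_atom(two, 0L, i)
        i <- i + 2L
      } else if (ch %in% ORGANIC_ONE) {
        add_atom(ch, 0L, i)
        i <- i + 1L
      } else {
        lin_error(sprintf("unsupported token '%s' (use brackets for this element)", ch), i)
      }
    } else {
      lin_error(sprintf("unsupported token '%s'", ch), i)
    }
  }
  if (length(stack)) lin_error("unmatched '('", n)
  open_digits <- names(ring_open)[!vapply(ring_open, is.null, TRUE)]
  if (length(open_digits)) {
    lin_error(sprintf("unclosed ring digit(s): %s", paste(open_digits, collapse = ",")), n)
  }
  if (!is.null(pending_order)) lin_error("dangling bond symbol", n)
  # Transfer ring annotations stashed on bond symbols.
  for (k in seq_along(bonds)) {
    r <- attr(bonds[[k]]$order, "ring")
    if (!is.null(r)) bonds[[k]]$ring <- r
  }
  list(atoms = atoms, bonds = bonds)
}

parse_annotation <- function(body, pos) {
  parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) lin_error(sprintf("bad annotation '{%s}'", body), pos)
  key <- parts[1L]; val <- parts[2L]
  if (key == "charge") {
    if (val == "any") return(list(kind = "charge", charge = NA_integer_))
    if (!grepl("^[+-]?[0-9]+$", val)) lin_error(sprintf("bad charge '%s'", val), pos)
    return(list(kind = "charge", charge = as.integer(val)))
  }
  if (key == "ring") {
    if (val == "acyclic") {
      return(list(kind = "ring", ring = list(type = "acyclic", min = NA_integer_, max = NA_integer_)))
    }
    m <- regmatches(val, regexec("^([0-9]*)-([0-9]*)$", val))[[1L]]
    if (length(m) == 0L || (!nzchar(m[2L]) && !nzchar(m[3L]))) {
      lin_error(sprintf("bad ring constraint '%s'", val), pos)
    }
    mn <- if (nzchar(m[2L])) as.integer(m[2L]) else NA_integer_
    mx <- if (nzchar(m[3L])) as.integer(m[3L]) else NA_integer_
    if (!is.na(mn) && mn < 3L) lin_error("ring size minimum must be >= 3", pos)
    if (!is.na(mn) && !is.na(mx) && mn > mx) lin_error("ring range min > max", pos)
    return(list(kind = "ring", ring = list(type = "range", min = mn, max = mx)))
  }
  lin_error(sprintf("unknown annotation key '%s'", key), pos)
}

#' Parse a molecule from linear notation
#'
#' @param notation A string in the notation subset described above (no query
#'   extensions).
#' @param name Optional molecule name.
#' @return A connected `molgraph`. Implicit hydrogens are not added.
#' @examples
#' parse_linear("C1CCCCC1")   # cyclohexane
#' parse_linear("C1=CC=CC=C1") # benzene, Kekule form
#' @export
parse_linear <- function(notation, name = "") {
  raw <- parse_linear_raw(notation, query = FALSE)
  if (!length(raw$atoms)) stop("empty notation", call. = FALSE)
  element <- vapply(raw$atoms, `[[`, "", "element")
  charge <- vapply(raw$atoms, `[[`, 0L, "charge")
  bonds <- raw_bonds_df(raw$bonds)
  molgraph(element, bonds, charge, name = name)
}

raw_bonds_df <- function(bonds) {
  if (!length(bonds)) return(empty_bonds())
  data.frame(
    a = vapply(bonds, `[[`, 0L, "a"),
    b = vapply(bonds, `[[`, 0L, "b"),
    order = vapply(bonds, function(b) as.integer(b$order), 0L)
  )
}
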