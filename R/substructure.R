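# 2D substructure search.
#
# Pipeline: the query is compiled from annotated linear notation into a
# query graph plus necessary-condition screens (element multiset, definite
# path-feature bits, largest ring-assembly size). Database connectivities
# failing a screen can never match and are skipped; survivors go to a
# breadth-first backtracking subgraph matcher: per-atom candidate lists are
# filtered by local predicates, iteratively refined by adjacency
# consistency, then assignments are completed by backtracking in
# most-constrained-first order. Matching is monomorphism: a query drawn
# acyclic may embed in a ring unless an explicit ring constraint forbids it.

#' Compile a substructure query
#'
#' @param spec Query in linear notation with optional extensions: `*`
#'   wildcard atom, `~` any-order bond, and annotations `{ring:MIN-MAX}`,
#'   `{ring:MIN-}`, `{ring:-MAX}`, `{ring:acyclic}`, `{charge:+N|-N|0|any}`
#'   attached to the preceding atom (or bond symbol, for ring constraints).
#'   A plainly written atom constrains formal charge to 0; use
#'   `{charge:any}` (or `*`) for charge-agnostic matching.
#' @param width,max_atoms Fingerprint parameters used for the derived
#'   feature-bit screen; must match the database searched.
#' @return An object of class `subquery` with the query graph and screens.
#' @export
compile_query <- function(spec, width = FP_WIDTH, max_atoms = FP_MAX_PATH_ATOMS) {
  raw <- parse_linear_raw(spec, query = TRUE)
  if (!length(raw$atoms)) stop("empty query", call. = FALSE)
  element <- vapply(raw$atoms, `[[`, "", "element")
  charge <- vapply(raw$atoms, `[[`, 0L, "charge")
  ring_con <- lapply(raw$atoms, `[[`, "ring")
  bonds <- raw_bonds_df(raw$bonds)
  bond_ring <- lapply(raw$bonds, `[[`, "ring")
  n <- length(element)
  comps <- graph_components(n, bonds)
  if (length(comps$sizes) > 1L) {
    stop("disconnected query: single-fragment queries only", call. = FALSE)
  }
  for (rc in c(ring_con, bond_ring)) {
    if (rc$type == "range" && !is.na(rc$min) && !is.na(rc$max) && rc$min > rc$max) {
      stop("contradictory ring constraint: min > max", call. = FALSE)
    }
  }
  q <- structure(
    list(element = element, charge = charge, ring_con = ring_con,
         bonds = bonds, bond_ring = bond_ring, spec = spec),
    class = "subquery"
  )
  q$screens <- query_screens(q, width, max_atoms)
  q
}

#' @export
print.subquery <- function(x, ...) {
  cat(sprintf("<subquery '%s': %d atoms, %d bonds, %d screen bits>\n",
              x$spec, length(x$element), nrow(x$bonds),
              length(x$screens$fp_bits)))
  invisible(x)
}

# Derived screens: element multiset of non-wildcard atoms, feature bits of
# fully definite paths, and the query's largest ring-assembly size.
query_screens <- function(q, width, max_atoms) {
  elem <- q$element[q$element != "*"]
  tab <- table(elem)
  elem_counts <- stats::setNames(as.integer(tab), names(tab))
  # Definite subgraph: atoms with known element and charge, bonds with a
  # definite order. Only paths wholly inside it yield sound feature bits.
  def_atom <- q$element != "*" & !is.na(q$charge)
  keep <- def_atom[q$bonds$a] & def_atom[q$bonds$b] & !is.na(q$bonds$order)
  bits <- integer(0)
  sub_atoms <- which(def_atom)
  if (length(sub_atoms)) {
    remap <- integer(length(q$element))
    remap[sub_atoms] <- seq_along(sub_atoms)
    bsub <- q$bonds[keep, , drop = FALSE]
    bsub$a <- remap[bsub$a]
    bsub$b <- remap[bsub$b]
    comps <- split_connectivities(q$element[sub_atoms], bsub, q$charge[sub_atoms])
    feats <- unlist(lapply(comps, enumerate_paths, max_atoms = max_atoms))
    bits <- sort(unique(feature_bit(unique(feats), width)))
  }
  # Ring assembly size from query topology (orders irrelevant).
  skel <- q$bonds
  skel$order <- rep(1L, nrow(skel))
  skel_mol <- molgraph(rep("C", length(q$element)), skel, check_connected = FALSE)
  ri <- compute_ring_info(skel_mol)
  list(elem_counts = elem_counts, fp_bits = bits, max_assembly = ri$max_assembly)
}

#' Screen test: can this entry possibly match?
#'
#' Sound necessary condition: returns `TRUE` whenever a true match exists.
#' Checks element-multiset containment, feature-bit containment, and (when
#' the query is cyclic) that the query's largest ring assembly is no larger
#' than the connectivity's.
#'
#' @param query A `subquery`.
#' @param entry_screens List with `elem_counts` (named integer vector),
#'   `fp_bits` (integer vector of set bits), `max_assembly` (integer), as
#'   stored per connectivity by [build_database()].
#' @return Logical.
#' @export
screen_pass <- function(query, entry_screens) {
  qe <- query$screens$elem_counts
  te <- entry_screens$elem_counts
  if (length(qe)) {
    have <- te[names(qe)]
    if (any(is.na(have)) || any(have < qe)) return(FALSE)
  }
  if (length(query$screens$fp_bits) &&
      !all(query$screens$fp_bits %in% entry_screens$fp_bits)) {
    return(FALSE)
  }
  if (query$screens$max_assembly > 0L &&
      query$screens$max_assembly > entry_screens$max_assembly) {
    return(FALSE)
  }
  TRUE
}

ring_con_ok <- function(rc, srs) {
  switch(rc$type,
    none = TRUE,
    acyclic = is.na(srs),
    range = !is.na(srs) &&
      (is.na(rc$min) || srs >= rc$min) &&
      (is.na(rc$max) || srs <= rc$max)
  )
}

#' Match a substructure query against one molecule
#'
#' Breadth-first backtracking: initial candidate lists per query atom
#' (element/charge/degree/ring-constraint filters), iterative adjacency
#' refinement, then backtracking assignment in most-constrained-first
#' order. Automorphic duplicate mappings are retained in `find_all` mode.
#'
#' @param query A `subquery`.
#' @param mol A `molgraph` target (ring info computed on demand or cached
#'   via [with_ring_info()]).
#' @param find_all If `TRUE`, return every injective mapping; otherwise stop
#'   at the first.
#' @return List of integer vectors; element `i` of a mapping is the target
#'   atom matched to query atom `i`. Empty list if no match.
#' @export
match_substructure <- function(query, mol, find_all = TRUE) {
  nq <- length(query$element)
  nt <- n_atoms(mol)
  if (nq > nt) return(list())
  ri <- ring_info(mol)
  bm <- bond_matrix(mol)
  bim <- bond_index_matrix(mol)
  tdeg <- atom_degree(mol)
  qdeg <- tabulate(c(query$bonds$a, query$bonds$b), nbins = nq)

  cands <- vector("list", nq)
  for (i in seq_len(nq)) {
    ok <- rep(TRUE, nt)
    if (query$element[i] != "*") ok <- ok & mol$element == query$element[i]
    if (!is.na(query$charge[i])) ok <- ok & mol$charge == query$charge[i]
    ok <- ok & tdeg >= qdeg[i]
    rc <- query$ring_con[[i]]
    if (rc$type != "none") {
      ok <- ok & vapply(seq_len(nt), function(t) ring_con_ok(rc, ri$atom_srs[t]), TRUE)
    }
    cands[[i]] <- which(ok)
    if (!length(cands[[i]])) return(list())
  }

  bond_ok <- function(k, t, u) {
    ord <- bm[t, u]
    if (ord == 0L) return(FALSE)
    qo <- query$bonds$order[k]
    if (!is.na(qo) && ord != qo) return(FALSE)
    rc <- query$bond_ring[[k]]
    if (rc$type != "none" && !ring_con_ok(rc, ri$bond_srs[bim[t, u]])) return(FALSE)
    TRUE
  }

  # adjacency refinement to a fixed point
  qb <- query$bonds
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(qb))) {
      for (dir in 1:2) {
        i <- if (dir == 1L) qb$a[k] else qb$b[k]
        j <- if (dir == 1L) qb$b[k] else qb$a[k]
        keep <- vapply(cands[[i]], function(t) {
          any(vapply(cands[[j]], function(u) u != t && bond_ok(k, t, u), TRUE))
        }, TRUE)
        if (!all(keep)) {
          cands[[i]] <- cands[[i]][keep]
          changed <- TRUE
          if (!length(cands[[i]])) return(list())
        }
      }
    }
    if (!changed) break
  }

  ord <- order(lengths(cands), seq_len(nq))
  # bonds incident to each query atom, split by whether the other endpoint
  # comes earlier in the assignment order
  rank_of <- integer(nq)
  rank_of[ord] <- seq_len(nq)
  results <- list()
  assigned <- integer(nq)
  used <- logical(nt)
  assign_next <- function(level) {
    if (level > nq) {
      results[[length(results) + 1L]] <<- assigned
      return(!find_all)  # TRUE aborts the search
    }
    i <- ord[level]
    for (t in cands[[i]]) {
      if (used[t]) next
      ok <- TRUE
      for (k in seq_len(nrow(qb))) {
        other <- if (qb$a[k] == i) qb$b[k] else if (qb$b[k] == i) qb$a[k] else next
        if (rank_of[other] < rank_of[i]) {
          if (!bond_ok(k, t, assigned[other])) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assigned[i] <<- t
      used[t] <<- TRUE
      done <- assign_next(level + 1L)
      used[t] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  assign_next(1L)
  results
}

#' Substructure search over a database
#'
#' Screens every stored connectivity, graph-matches the survivors, and
#' reports per-entry match counts. The number of screened-out and matched
#' connectivities is attached as attribute `counts` (and logged to stderr
#' by the CLI).
#'
#' @param query A `subquery` (or a query string, compiled on the fly with
#'   the database's fingerprint settings).
#' @param db A database from [build_database()].
#' @param find_all Count all mappings (`TRUE`) or stop at the first.
#' @param use_screens Debug flag; disabling screens must never change the
#'   hit set, only the work done.
#' @return Data frame `refcode`, `connectivity`, `n_mappings`, ordered by
#'   refcode then connectivity.
#' @export
substructure_search <- function(query, db, find_all = TRUE, use_screens = TRUE) {
  if (is.character(query)) {
    query <- compile_query(query, width = db$config$fp_width,
                           max_atoms = db$config$max_path_atoms)
  }
  conns <- db$tables$connectivities
  out <- list()
  screened_out <- 0L
  matched <- 0L
  for (r in seq_len(nrow(conns))) {
    scr <- list(elem_counts = conns$elem_counts[[r]],
                fp_bits = conns$bits[[r]],
                max_assembly = conns$max_assembly[r])
    if (use_screens && !screen_pass(query, scr)) {
      screened_out <- screened_out + 1L
      next
    }
    mol <- conns$graph[[r]]
    maps <- match_substructure(query, mol, find_all = find_all)
    if (length(maps)) {
      matched <- matched + 1L
      out[[length(out) + 1L]] <- data.frame(
        refcode = conns$refcode[r],
        connectivity = conns$connectivity[r],
        n_mappings = length(maps)
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(refcode = character(0), connectivity = integer(0),
               n_mappings = integer(0))
  }
  res <- res[order(res$refcode, res$connectivity), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "counts") <- list(screened_out = screened_out, matched = matched,
                              searched = nrow(conns) - screened_out)
  res
}
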