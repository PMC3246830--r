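# Independent brute-force oracles. These deliberately re-derive results by
# naive enumeration, sharing no code path with the package implementation.

# --- exhaustive subgraph-mapping oracle -------------------------------------
# Enumerates injective mappings query-atom-by-query-atom in index order,
# checking predicates and adjacency directly against the molecule tables.
oracle_mappings <- function(q, mol) {
  nq <- length(q$element)
  nt <- n_atoms(mol)
  if (nq > nt) return(list())
  ri <- compute_ring_info(mol)
  bm <- matrix(0L, nt, nt)
  srsm <- matrix(NA_integer_, nt, nt)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    bm[a, b] <- bm[b, a] <- mol$bonds$order[k]
    srsm[a, b] <- srsm[b, a] <- ri$bond_srs[k]
  }
  rc_ok <- function(rc, srs) {
    if (rc$type == "none") return(TRUE)
    if (rc$type == "acyclic") return(is.na(srs))
    !is.na(srs) && (is.na(rc$min) || srs >= rc$min) && (is.na(rc$max) || srs <= rc$max)
  }
  res <- list()
  rec <- function(map) {
    i <- length(map) + 1L
    if (i > nq) {
      res[[length(res) + 1L]] <<- map
      return(invisible())
    }
    for (t in setdiff(seq_len(nt), map)) {
      if (q$element[i] != "*" && mol$element[t] != q$element[i]) next
      if (!is.na(q$charge[i]) && mol$charge[t] != q$charge[i]) next
      if (!rc_ok(q$ring_con[[i]], ri$atom_srs[t])) next
      ok <- TRUE
      for (k in seq_len(nrow(q$bonds))) {
        a <- q$bonds$a[k]; b <- q$bonds$b[k]
        u <- if (b == i && a < i) map[a] else if (a == i && b < i) map[b] else next
        if (bm[t, u] == 0L) { ok <- FALSE; break }
        qo <- q$bonds$order[k]
        if (!is.na(qo) && bm[t, u] != qo) { ok <- FALSE; break }
        if (!rc_ok(q$bond_ring[[k]], srsm[t, u])) { ok <- FALSE; break }
      }
      if (!ok) next
      rec(c(map, t))
    }
  }
  rec(integer(0))
  res
}

map_key <- function(maps) sort(vapply(maps, paste, "", collapse = ","))

# --- brute-force smallest ring through an atom ------------------------------
# DFS over all simple cycles through v; independent of the per-bond BFS used
# by the package. Suitable for graphs of <= 14 atoms.
oracle_smallest_ring_atom <- function(mol, v) {
  nt <- n_atoms(mol)
  adj <- vector("list", nt)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  best <- Inf
  rec <- function(path) {
    cur <- path[length(path)]
    for (w in adj[[cur]]) {
      if (w == v && length(path) >= 3L) {
        best <<- min(best, length(path))
      } else if (!(w %in% path) && length(path) < best - 1L) {
        rec(c(path, w))
      }
    }
  }
  rec(v)
  if (is.finite(best)) as.integer(best) else NA_integer_
}

# --- linear text-scan oracle ------------------------------------------------
# Full scan over entry records, no index involved.
oracle_text_scan <- function(entries, field, term) {
  field_cols <- c(author = "authors", journal = "journal",
                  compound_name = "compound_name", synonyms = "synonyms",
                  habit = "habit", bioactivity = "bioactivity",
                  phase_transitions = "phase_transitions",
                  polymorphism = "polymorphism")
  cols <- if (identical(field, "all_text")) unname(field_cols) else field_cols[[field]]
  toks <- tokenize(term)
  hit <- vapply(entries, function(e) {
    any(vapply(cols, function(col) {
      etoks <- tokenize(e[[col]])
      if (length(toks) == 1L) return(toks %in% etoks)
      if (length(etoks) < length(toks)) return(FALSE)
      any(vapply(seq_len(length(etoks) - length(toks) + 1L), function(s) {
        all(etoks[s + seq_along(toks) - 1L] == toks)
      }, TRUE))
    }, TRUE))
  }, TRUE)
  sort(vapply(entries[hit], `[[`, "", "refcode"))
}

# --- brute-force similarity ranking ----------------------------------------
oracle_similarity <- function(query_bits, db, coefficient, top_k, min_coeff) {
  fps <- db$tables$fingerprints
  coeff <- vapply(seq_len(nrow(fps)), function(r) {
    bits <- fps$bits[[r]]
    i <- sum(query_bits %in% bits)
    if (coefficient == "tanimoto") {
      i / (length(query_bits) + length(bits) - i)
    } else {
      2 * i / (length(query_bits) + length(bits))
    }
  }, 0)
  df <- data.frame(refcode = fps$refcode, connectivity = fps$connectivity,
                   coefficient = coeff)
  df <- df[df$coefficient >= min_coeff, , drop = FALSE]
  df <- df[order(-df$coefficient, df$refcode, df$connectivity), , drop = FALSE]
  if (nrow(df) > top_k) df <- df[seq_len(top_k), , drop = FALSE]
  rownames(df) <- NULL
  df
}

table_to_counts <- function(mol) {
  tab <- table(mol$element)
  stats::setNames(as.integer(tab), names(tab))
}

# Small fixture database shared across tests (built once per run).
fixture_db_cached <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$db)) {
      cache$fx <- fixture_entries(fixture_spec())
      cache$db <- suppressWarnings(build_database(cache$fx$entries))
    }
    list(fx = cache$fx, db = cache$db)
  }
})
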