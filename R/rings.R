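# Ring perception.
#
# Three artifacts are derived from a connected molecular graph:
#   * a smallest set of smallest rings (SSSR) -- a minimum cycle basis,
#     selected deterministically;
#   * the smallest ring size through every atom and bond, computed
#     independently of the SSSR selection by a per-bond BFS;
#   * ring assemblies: connected components of the subgraph induced by ring
#     bonds (fused and spiro systems group together because components are
#     connected through shared atoms as well as shared bonds).

#' Compute ring information for a molecule
#'
#' @param mol A connected `molgraph`.
#' @return A list of class `ring_info`:
#'   \describe{
#'     \item{rings}{List of integer atom-index cycles (SSSR), each rotated so
#'       the smallest atom index comes first, traversed in the direction of
#'       its smaller second element.}
#'     \item{atom_srs}{Integer vector: smallest ring size through each atom
#'       (`NA` for acyclic atoms).}
#'     \item{bond_srs}{Integer vector, parallel to `mol$bonds`: smallest ring
#'       size through each bond (`NA` for acyclic bonds).}
#'     \item{assemblies}{List of lists with `atoms` (integer vector) and
#'       `size` (atom count) per fused/spiro ring system.}
#'     \item{max_assembly}{Largest assembly size in atoms (0 if acyclic).}
#'   }
#' @export
compute_ring_info <- function(mol) {
  n <- n_atoms(mol)
  nb <- n_bonds(mol)
  adj <- adjacency(mol)
  bond_srs <- rep(NA_integer_, nb)
  for (k in seq_len(nb)) {
    bond_srs[k] <- smallest_cycle_through_bond(mol, adj, k)
  }
  atom_srs <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    inc <- adj[[v]]
    if (nrow(inc) == 0L) next
    s <- bond_srs[inc[, "bond"]]
    if (all(is.na(s))) next
    atom_srs[v] <- min(s, na.rm = TRUE)
  }
  cyclomatic <- nb - n + 1L
  rings <- if (cyclomatic > 0L) select_sssr(mol, adj, cyclomatic) else list()
  assemblies <- ring_assemblies(mol, bond_srs)
  max_assembly <- if (length(assemblies)) max(vapply(assemblies, `[[`, 0L, "size")) else 0L
  structure(
    list(rings = rings, atom_srs = atom_srs, bond_srs = bond_srs,
         assemblies = assemblies, max_assembly = max_assembly),
    class = "ring_info"
  )
}

# Length of the shortest cycle containing bond k: remove the bond, BFS from
# one endpoint to the other; path length + 1, or NA if none.
smallest_cycle_through_bond <- function(mol, adj, k) {
  a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
  n <- n_atoms(mol)
  dist <- rep(NA_integer_, n)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v == b) break
    inc <- adj[[v]]
    for (i in seq_len(nrow(inc))) {
      if (inc[i, "bond"] == k) next
      w <- inc[i, "nbr"]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  if (is.na(dist[b])) NA_integer_ else dist[b] + 1L
}

# Deterministic minimum cycle basis: Horton candidate cycles (shortest cycle
# through each (vertex, edge) pair), sorted by (length, canonical atom
# tuple), then greedy GF(2) selection until the cyclomatic number is reached.
select_sssr <- function(mol, adj, cyclomatic) {
  n <- n_atoms(mol)
  nb <- n_bonds(mol)
  # All-pairs BFS shortest paths with deterministic parents (neighbors
  # visited in ascending order guarantee a canonical shortest-path tree).
  parent <- matrix(0L, n, n)  # parent[s, v]: predecessor of v on s->v path
  dist <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      inc <- adj[[v]]
      nbrs <- sort(inc[, "nbr"])
      for (w in nbrs) {
        if (is.na(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1L
          parent[s, w] <- v
          queue <- c(queue, w)
        }
      }
    }
  }
  path_to <- function(s, v) {
    p <- v
    while (v != s) {
      v <- parent[s, v]
      p <- c(v, p)
    }
    p
  }
  bm <- bond_index_matrix(mol)
  candidates <- list()
  seen <- character(0)
  for (v in seq_len(n)) {
    for (k in seq_len(nb)) {
      x <- mol$bonds$a[k]; y <- mol$bonds$b[k]
      if (is.na(dist[v, x]) || is.na(dist[v, y])) next
      px <- path_to(v, x)
      py <- path_to(v, y)
      cyc <- c(px, rev(py)[-length(py)])
      if (anyDuplicated(cyc)) next  # paths overlap: not a simple cycle
      if (length(cyc) < 3L) next
      cyc <- canonical_cycle(cyc)
      key <- paste(cyc, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      candidates[[length(candidates) + 1L]] <- cyc
    }
  }
  sizes <- lengths(candidates)
  keys <- vapply(candidates, function(cyc) {
    paste(formatC(cyc, width = 6, flag = "0"), collapse = ",")
  }, "")
  ord <- order(sizes, keys)
  candidates <- candidates[ord]
  # Greedy GF(2) independence over bond-incidence vectors, echelon form
  # keyed by pivot position.
  rows <- list()
  pivots <- integer(0)
  chosen <- list()
  for (cyc in candidates) {
    vec <- cycle_bond_vector(cyc, bm, nb)
    repeat {
      p <- which(vec)[1L]
      if (is.na(p)) break  # dependent on current basis
      j <- match(p, pivots)
      if (is.na(j)) {
        rows[[length(rows) + 1L]] <- vec
        pivots <- c(pivots, p)
        chosen[[length(chosen) + 1L]] <- cyc
        break
      }
      vec <- xor(vec, rows[[j]])
    }
    if (length(chosen) == cyclomatic) break
  }
  if (length(chosen) != cyclomatic) {
    stop("internal error: cycle basis incomplete")  # unreachable on valid graphs
  }
  chosen
}

bond_index_matrix <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  bd <- mol$bonds
  idx <- seq_len(nrow(bd))
  m[cbind(bd$a, bd$b)] <- idx
  m[cbind(bd$b, bd$a)] <- idx
  m
}

cycle_bond_vector <- function(cyc, bm, nb) {
  vec <- rep(FALSE, nb)
  m <- length(cyc)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    vec[bm[cyc[i], cyc[j]]] <- TRUE
  }
  vec
}

# Rotate/reflect a cycle to canonical form: smallest atom first, then the
# smaller of the two traversal directions.
canonical_cycle <- function(cyc) {
  m <- length(cyc)
  i <- which.min(cyc)
  fwd <- cyc[((seq_len(m) + i - 2L) %% m) + 1L]
  rev_c <- c(fwd[1L], rev(fwd[-1L]))
  if (paste(formatC(fwd, width = 6, flag = "0"), collapse = ",") <=
      paste(formatC(rev_c, width = 6, flag = "0"), collapse = ",")) fwd else rev_c
}

# Assemblies: connected components of the subgraph of ring bonds. Spiro
# systems merge because the components are computed over atoms.
ring_assemblies <- function(mol, bond_srs) {
  ring_bonds <- which(!is.na(bond_srs))
  if (!length(ring_bonds)) return(list())
  bd <- mol$bonds[ring_bonds, , drop = FALSE]
  atoms <- sort(unique(c(bd$a, bd$b)))
  remap <- integer(n_atoms(mol))
  remap[atoms] <- seq_along(atoms)
  sub <- data.frame(a = remap[bd$a], b = remap[bd$b], order = bd$order)
  comp <- graph_components(length(atoms), sub)$membership
  out <- list()
  for (c_id in sort(unique(comp))) {
    members <- atoms[comp == c_id]
    out[[length(out) + 1L]] <- list(atoms = members, size = length(members))
  }
  out
}

# Ring info with per-molecule memoization via attribute.
ring_info <- function(mol) {
  ri <- attr(mol, "ring_info")
  if (is.null(ri)) ri <- compute_ring_info(mol)
  ri
}

#' Attach cached ring information to a molecule
#'
#' @param mol A `molgraph`.
#' @return `mol` with a `ring_info` attribute for reuse by the matcher.
#' @export
with_ring_info <- function(mol) {
  attr(mol, "ring_info") <- compute_ring_info(mol)
  mol
}
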