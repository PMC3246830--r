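# Molecular graph model.
#
# A molecule is a simple, undirected, connected graph: atoms carry an element
# symbol and a formal charge; bonds carry an order (1 = single, 2 = double,
# 3 = triple). Atom indices are 1-based. Coordinates are never stored: this
# is a 2D-connectivity model throughout.

#' Construct a molecular graph
#'
#' @param element Character vector of element symbols, one per atom.
#' @param bonds Data frame with integer columns `a`, `b`, `order` (1, 2 or 3).
#'   Endpoint pairs are normalized so that `a < b`.
#' @param charge Integer vector of formal charges (default all zero).
#' @param name Molecule name.
#' @param check_connected If `TRUE` (default), require a single connectivity.
#' @return An object of class `molgraph` with fields `element`, `charge`,
#'   `bonds` and `name`.
#' @export
molgraph <- function(element, bonds = empty_bonds(), charge = NULL, name = "",
                     check_connected = TRUE) {
  element <- as.character(element)
  n <- length(element)
  if (is.null(charge)) charge <- integer(n)
  charge <- as.integer(charge)
  stopifnot(length(charge) == n)
  bad <- !is_element(element)
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(element[bad]), collapse = ", "))
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0L) bonds <- empty_bonds()
  bonds$a <- as.integer(bonds$a)
  bonds$b <- as.integer(bonds$b)
  bonds$order <- as.integer(bonds$order)
  if (any(bonds$a == bonds$b)) stop("self-bond not allowed")
  if (nrow(bonds) > 0L &&
      (min(bonds$a, bonds$b) < 1L || max(bonds$a, bonds$b) > n)) {
    stop("bond endpoint out of range")
  }
  if (!all(bonds$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  swap <- bonds$a > bonds$b
  tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
  key <- paste(bonds$a, bonds$b)
  if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  bonds <- bonds[order(bonds$a, bonds$b), c("a", "b", "order"), drop = FALSE]
  rownames(bonds) <- NULL
  mol <- structure(
    list(element = element, charge = charge, bonds = bonds, name = as.character(name)),
    class = "molgraph"
  )
  if (check_connected && n > 0L && length(graph_components(n, bonds)$sizes) > 1L) {
    stop("molecule graph must be connected (split components first)")
  }
  mol
}

empty_bonds <- function() {
  data.frame(a = integer(0), b = integer(0), order = integer(0))
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph%s: %d atoms, %d bonds>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              n_atoms(x), n_bonds(x)))
  invisible(x)
}

#' Number of atoms / bonds
#' @param mol A `molgraph`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) length(mol$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' Atom degrees
#' @param mol A `molgraph`.
#' @return Integer vector: number of bonds incident to each atom.
#' @export
atom_degree <- function(mol) {
  tabulate(c(mol$bonds$a, mol$bonds$b), nbins = n_atoms(mol))
}

# Adjacency list: for each atom, matrix with columns nbr, order, bond.
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(matrix(integer(0), 0, 3,
                         dimnames = list(NULL, c("nbr", "order", "bond")))), n)
  bd <- mol$bonds
  if (nrow(bd) == 0L) return(adj)
  ends <- c(bd$a, bd$b)
  nbrs <- c(bd$b, bd$a)
  ords <- c(bd$order, bd$order)
  ids <- c(seq_len(nrow(bd)), seq_len(nrow(bd)))
  o <- order(ends, nbrs)
  ends <- ends[o]; nbrs <- nbrs[o]; ords <- ords[o]; ids <- ids[o]
  split_idx <- split(seq_along(ends), ends)
  for (k in names(split_idx)) {
    i <- split_idx[[k]]
    adj[[as.integer(k)]] <- cbind(nbr = nbrs[i], order = ords[i], bond = ids[i])
  }
  adj
}

# Connected components from an edge list; returns membership and sizes.
graph_components <- function(n, bonds) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  list(membership = comp, sizes = as.integer(table(comp)))
}

#' Split a (possibly disconnected) atom/bond set into connectivities
#'
#' @param element,bonds,charge,name As in [molgraph()], but the graph may be
#'   disconnected.
#' @return List of connected `molgraph` objects, ordered by their smallest
#'   original atom index.
#' @export
split_connectivities <- function(element, bonds, charge = NULL, name = "") {
  n <- length(element)
  if (is.null(charge)) charge <- integer(n)
  comp <- graph_components(n, bonds)$membership
  out <- list()
  for (c_id in sort(unique(comp))) {
    idx <- which(comp == c_id)
    remap <- integer(n)
    remap[idx] <- seq_along(idx)
    keep <- bonds$a %in% idx & bonds$b %in% idx
    bsub <- bonds[keep, , drop = FALSE]
    bsub$a <- remap[bsub$a]
    bsub$b <- remap[bsub$b]
    out[[length(out) + 1L]] <- molgraph(element[idx], bsub, charge[idx], name)
  }
  out
}

#' Remove explicit hydrogen atoms
#'
#' The package works on hydrogen-suppressed graphs: explicit H atoms read
#' from file are dropped before fingerprinting and matching. Hydrogens are
#' removed together with their bonds; if removal would disconnect the graph
#' (it cannot, since H is terminal in a simple graph unless bridging), each
#' surviving component is returned separately by the caller.
#'
#' @param mol A `molgraph`.
#' @return A `molgraph` without H atoms. An all-hydrogen molecule returns an
#'   empty graph.
#' @export
suppress_hydrogens <- function(mol) {
  keep <- which(mol$element != "H")
  if (length(keep) == n_atoms(mol)) return(mol)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  bd <- mol$bonds
  bd <- bd[bd$a %in% keep & bd$b %in% keep, , drop = FALSE]
  bd$a <- remap[bd$a]
  bd$b <- remap[bd$b]
  molgraph(mol$element[keep], bd, mol$charge[keep], mol$name,
           check_connected = FALSE)
}

#' Permute atom indices
#'
#' Relabels atoms by `perm` (atom `i` becomes atom `perm[i]`). Used in tests
#' to assert that fingerprints and hit sets do not depend on atom order.
#'
#' @param mol A `molgraph`.
#' @param perm A permutation of `seq_len(n_atoms(mol))`.
#' @return The relabeled `molgraph`.
#' @export
permute_atoms <- function(mol, perm) {
  perm <- as.integer(perm)
  stopifnot(length(perm) == n_atoms(mol), all(sort(perm) == seq_len(n_atoms(mol))))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  bd <- mol$bonds
  bd$a <- perm[bd$a]
  bd$b <- perm[bd$b]
  molgraph(mol$element[inv], bd, mol$charge[inv], mol$name)
}

# Dense bond-order lookup matrix (0 = no bond); for small molecule graphs.
bond_matrix <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  bd <- mol$bonds
  m[cbind(bd$a, bd$b)] <- bd$order
  m[cbind(bd$b, bd$a)] <- bd$order
  m
}

# Element multiset as a named integer vector (sorted by symbol).
element_counts <- function(mol) {
  tab <- table(mol$element)
  stats::setNames(as.integer(tab), names(tab))
}
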