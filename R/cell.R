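# Unit cells and reduced-cell searching.
#
# Reduction follows the Krivy-Gruber (1976) iteration on the metric scalars
# (A, B, C, xi, eta, zeta) = (a^2, b^2, c^2, 2bc cos(alpha), 2ac cos(beta),
# 2ab cos(gamma)), with epsilon-stabilized comparisons (eps proportional to
# volume^(2/3)) to avoid the well-known numerical instabilities of the
# Niggli conditions. The change of basis is tracked as an integer matrix of
# determinant +/-1; the metric is recomputed from it at every step, so the
# scalar state can never drift from the transformation.
#
# Because reduced-cell angles are unstable near decision boundaries, a
# query is expanded into a set of "nearly Buerger reduced" cells: unimodular
# images (entries in {-1,0,1}) of the reduced basis that still satisfy the
# Buerger shortest-vector conditions within tolerance and stay inside an
# instability window around the Niggli parameters. Matching a candidate
# against any member of that set, on lengths AND angles, gives an
# angle-aware search that rejects lattices a lengths-only comparison would
# conflate.

#' Construct a unit cell
#'
#' @param a,b,c Cell lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180); the
#'   metric tensor must be positive definite.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha, beta, gamma) {
  p <- as.numeric(c(a, b, c, alpha, beta, gamma))
  if (any(!is.finite(p))) stop("non-finite cell parameter", call. = FALSE)
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive", call. = FALSE)
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  cell <- structure(
    list(a = p[1], b = p[2], c = p[3], alpha = p[4], beta = p[5], gamma = p[6]),
    class = "unit_cell"
  )
  if (!is.finite(cell_volume(cell)) || cell_volume(cell) <= 0) {
    stop("degenerate cell: metric tensor not positive definite", call. = FALSE)
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell: a=%.4f b=%.4f c=%.4f alpha=%.3f beta=%.3f gamma=%.3f>\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

cell_params <- function(cell) {
  c(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
}

#' Metric tensor of a cell
#' @param cell A `unit_cell`.
#' @return 3x3 symmetric matrix of basis-vector dot products.
#' @export
cell_metric <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r); cg <- cos(cell$gamma * d2r)
  g <- matrix(c(
    cell$a^2, cell$a * cell$b * cg, cell$a * cell$c * cb,
    cell$a * cell$b * cg, cell$b^2, cell$b * cell$c * ca,
    cell$a * cell$c * cb, cell$b * cell$c * ca, cell$c^2
  ), 3, 3)
  g
}

metric_to_cell <- function(g) {
  a <- sqrt(g[1, 1]); b <- sqrt(g[2, 2]); c <- sqrt(g[3, 3])
  r2d <- 180 / pi
  clamp <- function(x) pmin(1, pmax(-1, x))
  unit_cell(a, b, c,
            acos(clamp(g[2, 3] / (b * c))) * r2d,
            acos(clamp(g[1, 3] / (a * c))) * r2d,
            acos(clamp(g[1, 2] / (a * b))) * r2d)
}

#' Cell volume
#' @param cell A `unit_cell`.
#' @return Volume in cubic Angstrom (`NaN` for a degenerate metric).
#' @export
cell_volume <- function(cell) {
  det_g <- det(cell_metric(cell))
  if (det_g <= 0) return(NaN)
  sqrt(det_g)
}

#' Transform a cell by an integer change of basis
#'
#' @param cell A `unit_cell`.
#' @param m Integer 3x3 matrix with determinant +/-1 (rows express the new
#'   basis vectors in the old basis).
#' @return The transformed `unit_cell` (same lattice, same volume).
#' @export
transform_cell <- function(cell, m) {
  m <- matrix(as.numeric(m), 3, 3)
  if (abs(abs(det(m)) - 1) > 1e-9) stop("transform must be unimodular", call. = FALSE)
  metric_to_cell(m %*% cell_metric(cell) %*% t(m))
}

#' Niggli reduction
#'
#' Krivy-Gruber iteration with epsilon-stabilized comparisons. Idempotent;
#' preserves the lattice (and hence the volume) exactly up to floating
#' rounding.
#'
#' @param cell A `unit_cell`.
#' @param eps Comparison stabilizer; default `1e-5 * volume^(2/3)`.
#' @return A list of class `reduced_cell`: `cell` (the reduced
#'   `unit_cell`), `niggli_type` (`"I"` if all reduced angles < 90, else
#'   `"II"`), and `basis` (integer matrix, det +/-1, mapping the input basis
#'   to the reduced basis).
#' @export
niggli_reduce <- function(cell, eps = NULL) {
  vol <- cell_volume(cell)
  if (!is.finite(vol) || vol <= 0) {
    stop("degenerate metric: cannot reduce", call. = FALSE)
  }
  if (is.null(eps)) eps <- 1e-5 * vol^(2 / 3)
  g0 <- cell_metric(cell)
  m <- diag(3)
  scalars <- function(g) {
    list(A = g[1, 1], B = g[2, 2], C = g[3, 3],
         xi = 2 * g[2, 3], eta = 2 * g[1, 3], zeta = 2 * g[1, 2])
  }
  apply_t <- function(tm) {
    m <<- tm %*% m
  }
  gt <- function(x, y) x > y + eps
  eqv <- function(x, y) abs(x - y) <= eps
  sgn <- function(x) if (x >= 0) 1 else -1
  for (iter in seq_len(1000L)) {
    g <- m %*% g0 %*% t(m)
    s <- scalars(g)
    A <- s$A; B <- s$B; C <- s$C; xi <- s$xi; eta <- s$eta; zeta <- s$zeta
    # A1: order A <= B
    if (gt(A, B) || (eqv(A, B) && gt(abs(xi), abs(eta)))) {
      apply_t(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE))
      next
    }
    # A2: order B <= C
    if (gt(B, C) || (eqv(B, C) && gt(abs(eta), abs(zeta)))) {
      apply_t(matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), 3, 3, byrow = TRUE))
      next
    }
    # sign classification with eps
    l <- if (xi > eps) 1L else if (xi < -eps) -1L else 0L
    mm <- if (eta > eps) 1L else if (eta < -eps) -1L else 0L
    nn <- if (zeta > eps) 1L else if (zeta < -eps) -1L else 0L
    if (l * mm * nn == 1L) {
      # A3: make all positive
      sx <- if (l < 0L) -1 else 1
      sy <- if (mm < 0L) -1 else 1
      sz <- if (nn < 0L) -1 else 1
      i <- sy * sz; j <- sx * sz; k <- sx * sy
      if (!(i == 1 && j == 1 && k == 1)) {
        apply_t(diag(c(i, j, k)))
        next
      }
    } else {
      # A4: make all non-positive
      t_ <- c(if (l > 0L) -1 else 1, if (mm > 0L) -1 else 1, if (nn > 0L) -1 else 1)
      if (prod(t_) == -1) {
        z <- which(c(l, mm, nn) == 0L)
        if (length(z)) t_[z[1L]] <- -t_[z[1L]] else {
          # unreachable: odd positives implies product 1 handled by A3
          stop("sign normalization failed")
        }
      }
      # t_ are the target multipliers jk, ik, ij; recover i,j,k
      i <- t_[2L] * t_[3L]; j <- t_[1L] * t_[3L]; k <- t_[1L] * t_[2L]
      if (!(i == 1 && j == 1 && k == 1)) {
        apply_t(diag(c(i, j, k)))
        next
      }
    }
    # A5
    if (gt(abs(xi), B) || (eqv(xi, B) && 2 * eta < zeta - eps) ||
        (eqv(xi, -B) && zeta < -eps)) {
      sx <- sgn(xi)
      apply_t(matrix(c(1, 0, 0, 0, 1, 0, 0, -sx, 1), 3, 3, byrow = TRUE))
      next
    }
    # A6
    if (gt(abs(eta), A) || (eqv(eta, A) && 2 * xi < zeta - eps) ||
        (eqv(eta, -A) && zeta < -eps)) {
      sy <- sgn(eta)
      apply_t(matrix(c(1, 0, 0, 0, 1, 0, -sy, 0, 1), 3, 3, byrow = TRUE))
      next
    }
    # A7
    if (gt(abs(zeta), A) || (eqv(zeta, A) && 2 * xi < eta - eps) ||
        (eqv(zeta, -A) && eta < -eps)) {
      sz <- sgn(zeta)
      apply_t(matrix(c(1, 0, 0, -sz, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
      next
    }
    # A8
    tot <- xi + eta + zeta + A + B
    if (tot < -eps || (eqv(tot, 0) && 2 * (A + eta) + zeta > eps)) {
      apply_t(matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 1), 3, 3, byrow = TRUE))
      next
    }
    red <- metric_to_cell(g)
    type <- if (red$alpha < 90 && red$beta < 90 && red$gamma < 90) "I" else "II"
    storage.mode(m) <- "integer"
    return(structure(list(cell = red, niggli_type = type, basis = m),
                     class = "reduced_cell"))
  }
  stop("Niggli reduction did not converge within 1000 steps", call. = FALSE)
}

#' @export
print.reduced_cell <- function(x, ...) {
  cat(sprintf("<reduced_cell type %s> ", x$niggli_type))
  print(x$cell)
  invisible(x)
}

#' Cell-matching tolerances
#'
#' @param rel_length Relative tolerance on each reduced length (default 0.01).
#' @param abs_angle Absolute tolerance on each reduced angle, degrees
#'   (default 1.0).
#' @return A `cell_tolerance` object.
#' @export
cell_tolerance <- function(rel_length = 0.01, abs_angle = 1.0) {
  stopifnot(rel_length >= 0, abs_angle >= 0)
  structure(list(rel_length = rel_length, abs_angle = abs_angle),
            class = "cell_tolerance")
}

# All 3x3 unimodular matrices with entries in {-1,0,1}; cached per session.
.unimodular_cache <- new.env(parent = emptyenv())

unimodular_111 <- function() {
  if (!is.null(.unimodular_cache$m)) return(.unimodular_cache$m)
  vals <- c(-1L, 0L, 1L)
  grid <- as.matrix(expand.grid(rep(list(vals), 9L)))
  keep <- apply(grid, 1L, function(v) {
    d <- det(matrix(v, 3, 3))
    abs(abs(d) - 1) < 0.5
  })
  ms <- lapply(which(keep), function(r) matrix(grid[r, ], 3, 3))
  .unimodular_cache$m <- ms
  ms
}

#' Nearly-Buerger reduced cell set
#'
#' The Niggli reduced cell of `cell` plus every unimodular image (entries in
#' -1..1) of the reduced basis that (a) still satisfies the Buerger
#' shortest-vector conditions within tolerance and (b) differs from the
#' Niggli parameters only within an instability window of twice the
#' tolerance. Cells are deduplicated on parameters rounded to 1e-6.
#'
#' @param cell A `unit_cell`.
#' @param tol A `cell_tolerance`.
#' @return List of `unit_cell`s; the first is the Niggli cell itself.
#' @export
nearly_buerger_set <- function(cell, tol = cell_tolerance()) {
  red <- niggli_reduce(cell)
  rp <- cell_params(red$cell)
  g <- cell_metric(red$cell)
  out <- list(red$cell)
  seen <- paste(sprintf("%.6f", rp), collapse = ",")
  len_win <- 2 * tol$rel_length
  ang_win <- 2 * tol$abs_angle
  for (u in unimodular_111()) {
    g2 <- u %*% g %*% t(u)
    A <- g2[1, 1]; B <- g2[2, 2]; C <- g2[3, 3]
    # Buerger main conditions within tolerance (on squared lengths)
    slack <- 2 * tol$rel_length
    if (A > B * (1 + slack) || B > C * (1 + slack)) next
    if (abs(2 * g2[2, 3]) > B * (1 + slack) ||
        abs(2 * g2[1, 3]) > A * (1 + slack) ||
        abs(2 * g2[1, 2]) > A * (1 + slack)) next
    cand <- metric_to_cell(g2)
    cp <- cell_params(cand)
    if (any(abs(cp[1:3] - rp[1:3]) > len_win * rp[1:3])) next
    if (any(abs(cp[4:6] - rp[4:6]) > ang_win)) next
    key <- paste(sprintf("%.6f", cp), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- cand
  }
  out
}

# Compare two parameter sets under tolerance, trying axis permutations that
# respect length ordering ties.
params_match <- function(p, q, tol, lengths_only = FALSE) {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) {
    lp <- p[1:3][pm]; ap <- p[4:6][pm]
    if (any(abs(lp - q[1:3]) > tol$rel_length * pmax(lp, q[1:3]))) next
    if (!lengths_only && any(abs(ap - q[4:6]) > tol$abs_angle)) next
    return(TRUE)
  }
  FALSE
}

#' Tolerance-based reduced-cell match
#'
#' `TRUE` iff some member of the query's nearly-Buerger set agrees with the
#' candidate reduced cell on all three lengths (relative tolerance) and all
#' three angles (absolute tolerance). Lengths-only matching is available as
#' a debug mode and is deliberately weaker.
#'
#' @param query A `unit_cell` (raw, will be reduced internally).
#' @param candidate A reduced `unit_cell` (e.g. from the database).
#' @param tol A `cell_tolerance`.
#' @param lengths_only Ignore angles (legacy behavior; more false positives).
#' @return Logical.
#' @export
cells_match <- function(query, candidate, tol = cell_tolerance(),
                        lengths_only = FALSE) {
  members <- nearly_buerger_set(query, tol)
  qp <- cell_params(candidate)
  for (memb in members) {
    if (params_match(cell_params(memb), qp, tol, lengths_only)) return(TRUE)
  }
  FALSE
}

#' Reduced-cell search over a database
#'
#' @param query A `unit_cell`.
#' @param db A database from [build_database()] (reduced cells precomputed).
#' @param tol A `cell_tolerance`.
#' @param lengths_only Debug flag: match on reduced lengths only.
#' @return Data frame `refcode` plus the stored reduced parameters of each
#'   hit, ordered by refcode. Entries without cells are skipped.
#' @export
reduced_cell_search <- function(query, db, tol = cell_tolerance(),
                                lengths_only = FALSE) {
  cells <- db$tables$cells
  empty <- data.frame(refcode = character(0), red_a = numeric(0),
                      red_b = numeric(0), red_c = numeric(0),
                      red_alpha = numeric(0), red_beta = numeric(0),
                      red_gamma = numeric(0))
  if (is.null(cells) || nrow(cells) == 0L) return(empty)
  members <- nearly_buerger_set(query, tol)
  hits <- logical(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    qp <- as.numeric(cells[r, c("red_a", "red_b", "red_c",
                                "red_alpha", "red_beta", "red_gamma")])
    for (memb in members) {
      if (params_match(cell_params(memb), qp, tol, lengths_only)) {
        hits[r] <- TRUE
        break
      }
    }
  }
  res <- cells[hits, c("refcode", "red_a", "red_b", "red_c",
                       "red_alpha", "red_beta", "red_gamma"), drop = FALSE]
  res <- res[order(res$refcode), , drop = FALSE]
  rownames(res) <- NULL
  res
}
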