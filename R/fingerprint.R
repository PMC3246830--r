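# Path-based molecular fingerprints.
#
# Every simple bonded path of 1..10 atoms in a connectivity is encoded as a
# canonical feature string ("C-C=N", with a charge suffix per atom when it
# is nonzero, e.g. "N+1"), hashed with 32-bit FNV-1a, and folded modulo a
# fixed width of 2040 bits. Fingerprints are binary (a bit is set iff at
# least one feature hashes to it); this makes them reusable as sound
# necessary-condition screens for substructure search. By construction the
# features carry no cyclicity information (hexane and cyclohexane are
# indistinguishable) and are element based (F and Cl are distinct).

FP_WIDTH <- 2040L
FP_MAX_PATH_ATOMS <- 10L

BOND_SYMBOL <- c("-", "=", "#")

atom_token <- function(element, charge) {
  suffix <- ifelse(charge > 0L, paste0("+", charge),
                   ifelse(charge < 0L, as.character(charge), ""))
  paste0(element, suffix)
}

#' Enumerate canonical path features of a molecule
#'
#' All simple bonded paths of 1 to `max_atoms` atoms, encoded as alternating
#' element(bond)element strings, each in the lexicographically smaller of
#' its two read directions (byte order).
#'
#' @param mol A `molgraph`.
#' @param max_atoms Maximum number of atoms per path (default 10).
#' @return Sorted character vector of distinct canonical features.
#' @export
enumerate_paths <- function(mol, max_atoms = FP_MAX_PATH_ATOMS) {
  stopifnot(max_atoms >= 1L)
  n <- n_atoms(mol)
  if (n == 0L) return(character(0))
  atoks <- atom_token(mol$element, mol$charge)
  adj <- adjacency(mol)
  acc <- new.env(parent = emptyenv())
  acc$fwd <- character(0)
  acc$rev <- character(0)
  visited <- logical(n)
  walk <- function(v, tokens, depth) {
    acc$fwd <- c(acc$fwd, paste(tokens, collapse = ""))
    acc$rev <- c(acc$rev, paste(rev(tokens), collapse = ""))
    if (depth == max_atoms) return(invisible())
    inc <- adj[[v]]
    for (i in seq_len(nrow(inc))) {
      w <- inc[i, "nbr"]
      if (visited[w]) next
      visited[w] <<- TRUE
      walk(w, c(tokens, BOND_SYMBOL[inc[i, "order"]], atoks[w]), depth + 1L)
      visited[w] <<- FALSE
    }
  }
  for (s in seq_len(n)) {
    visited[s] <- TRUE
    walk(s, atoks[s], 1L)
    visited[s] <- FALSE
  }
  # canonical direction: byte-wise smaller of forward/reverse
  canon <- ifelse(cmp_bytes(acc$fwd, acc$rev) <= 0L, acc$fwd, acc$rev)
  sort(unique(canon), method = "radix")
}

# Byte-order string comparison (locale independent, via radix sort ranks):
# -1, 0, or 1 per pair.
cmp_bytes <- function(x, y) {
  n <- length(x)
  v <- c(x, y)
  pos <- integer(2L * n)
  pos[order(v, method = "radix")] <- seq_len(2L * n)
  ifelse(x == y, 0L, ifelse(pos[seq_len(n)] < pos[n + seq_len(n)], -1L, 1L))
}

#' Hash a feature string to a bit index
#'
#' 32-bit FNV-1a over the UTF-8 bytes of the canonical feature string,
#' folded modulo `width`. Deterministic and platform independent; exactly
#' one bit per feature.
#'
#' @param feature Character vector of feature strings.
#' @param width Fingerprint width (default 2040).
#' @return Integer vector of 0-based bit indices in `[0, width)`.
#' @export
feature_bit <- function(feature, width = FP_WIDTH) {
  stopifnot(width >= 1L)
  as.integer(fnv1a32(feature) %% width)
}

# Vectorized 32-bit FNV-1a; arithmetic kept exact in doubles.
fnv1a32 <- function(s) {
  n <- length(s)
  if (n == 0L) return(numeric(0))
  raws <- lapply(s, function(x) as.integer(charToRaw(x)))
  lens <- lengths(raws)
  maxlen <- max(lens, 1L)
  bmat <- matrix(0L, n, maxlen)
  for (i in seq_len(n)) {
    if (lens[i]) bmat[i, seq_len(lens[i])] <- raws[[i]]
  }
  h <- rep(2166136261, n)
  prime <- 16777619
  for (j in seq_len(maxlen)) {
    active <- j <= lens
    if (!any(active)) break
    low <- h %% 256
    hx <- h - low + bitwXor(as.integer(low), bmat[, j])
    hi <- hx %/% 65536
    lo <- hx %% 65536
    hnew <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
    h[active] <- hnew[active]
  }
  h
}

#' Compute the 2040-bit fingerprint of a connectivity
#'
#' @param mol A connected, non-empty `molgraph`.
#' @param width Fingerprint width in bits (default 2040).
#' @param max_atoms Maximum path length in atoms (default 10).
#' @return An object of class `bitfp`: list with `bits` (sorted 0-based
#'   indices of set bits) and `width`.
#' @export
fingerprint <- function(mol, width = FP_WIDTH, max_atoms = FP_MAX_PATH_ATOMS) {
  if (n_atoms(mol) == 0L) stop("empty connectivity", call. = FALSE)
  feats <- enumerate_paths(mol, max_atoms)
  bitfp(feature_bit(feats, width), width)
}

#' Construct a fingerprint from bit indices
#'
#' @param bits Integer vector of 0-based set-bit indices.
#' @param width Width in bits.
#' @return A `bitfp`.
#' @export
bitfp <- function(bits, width = FP_WIDTH) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= width)) {
    stop("bit index out of range")
  }
  structure(list(bits = bits, width = as.integer(width)), class = "bitfp")
}

#' @export
print.bitfp <- function(x, ...) {
  cat(sprintf("<bitfp: %d/%d bits set>\n", length(x$bits), x$width))
  invisible(x)
}

#' Fingerprint popcount
#' @param fp A `bitfp`.
#' @return Number of set bits.
#' @export
popcount <- function(fp) length(fp$bits)

check_widths <- function(a, b) {
  if (a$width != b$width) stop("fingerprint width mismatch", call. = FALSE)
}

#' Tanimoto and Dice similarity coefficients
#'
#' Both coefficients lie in `[0, 1]`: 0 means no shared set bits, 1 means
#' identical fingerprint representations. Two all-zero fingerprints are
#' identical representations and score 1 (with a warning, since a non-empty
#' molecule always sets at least one bit).
#'
#' @param a,b `bitfp` objects of equal width.
#' @return Numeric coefficient.
#' @export
tanimoto <- function(a, b) {
  check_widths(a, b)
  if (!length(a$bits) && !length(b$bits)) {
    warning("both fingerprints empty: identical representations, coefficient 1")
    return(1)
  }
  inter <- length(intersect(a$bits, b$bits))
  inter / (length(a$bits) + length(b$bits) - inter)
}

#' @rdname tanimoto
#' @export
dice <- function(a, b) {
  check_widths(a, b)
  if (!length(a$bits) && !length(b$bits)) {
    warning("both fingerprints empty: identical representations, coefficient 1")
    return(1)
  }
  2 * length(intersect(a$bits, b$bits)) / (length(a$bits) + length(b$bits))
}

#' Ranked fingerprint similarity search
#'
#' Scores the query against every stored connectivity fingerprint (read from
#' the database, never recomputed) and returns hits sorted by coefficient
#' descending, ties broken by refcode then connectivity index.
#'
#' @param query A `molgraph` query molecule.
#' @param db A database built by [build_database()].
#' @param coefficient `"tanimoto"` or `"dice"`.
#' @param top_k Maximum number of hits returned (default 10).
#' @param min_coeff Minimum coefficient to report (default 0).
#' @return Data frame with columns `refcode`, `connectivity`, `coefficient`.
#' @export
similarity_search <- function(query, db, coefficient = c("tanimoto", "dice"),
                              top_k = 10L, min_coeff = 0) {
  coefficient <- match.arg(coefficient)
  scorer <- if (coefficient == "tanimoto") tanimoto else dice
  fps <- db$tables$fingerprints
  if (is.null(fps) || nrow(fps) == 0L) {
    return(data.frame(refcode = character(0), connectivity = integer(0),
                      coefficient = numeric(0)))
  }
  qfp <- fingerprint(query, width = db$config$fp_width,
                     max_atoms = db$config$max_path_atoms)
  coeff <- vapply(fps$bits, function(bits) {
    scorer(qfp, bitfp(bits, db$config$fp_width))
  }, 0)
  res <- data.frame(refcode = fps$refcode, connectivity = fps$connectivity,
                    coefficient = coeff)
  res <- res[res$coefficient >= min_coeff, , drop = FALSE]
  res <- res[order(-res$coefficient, res$refcode, res$connectivity), , drop = FALSE]
  if (nrow(res) > top_k) res <- res[seq_len(top_k), , drop = FALSE]
  rownames(res) <- NULL
  res
}
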