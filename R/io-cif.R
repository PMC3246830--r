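# Minimal CIF reading: unit-cell parameters only.

CIF_CELL_TAGS <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                   "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")

#' Read unit-cell parameters from a minimal CIF stream
#'
#' Extracts the six cell data items (`_cell_length_a` ... `_cell_angle_gamma`).
#' Parenthesized standard uncertainties are stripped. No other CIF content
#' (symmetry, coordinates, loops) is interpreted.
#'
#' @param input A file path, connection, or character vector of lines.
#' @return A `unit_cell` (lengths in Angstrom, angles in degrees).
#' @export
read_cif_cell <- function(input) {
  lines <- read_input_lines(input)
  vals <- stats::setNames(rep(NA_real_, 6L), CIF_CELL_TAGS)
  for (tag in CIF_CELL_TAGS) {
    pat <- paste0("^\\s*", tag, "\\s+(\\S+)")
    hit <- regmatches(lines, regexec(pat, lines))
    hit <- hit[lengths(hit) > 0L]
    if (length(hit)) {
      raw <- hit[[1L]][2L]
      num <- sub("\\(.*\\)$", "", raw)  # strip standard uncertainty
      v <- suppressWarnings(as.numeric(num))
      if (is.na(v)) stop(sprintf("unparseable value for %s: '%s'", tag, raw), call. = FALSE)
      vals[tag] <- v
    }
  }
  missing <- names(vals)[is.na(vals)]
  if (length(missing)) {
    stop("missing ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unit_cell(vals[1L], vals[2L], vals[3L], vals[4L], vals[5L], vals[6L])
}

#' Write a minimal CIF file for a unit cell
#'
#' @param cell A `unit_cell`.
#' @param path Output path; if `NULL` the lines are returned invisibly.
#' @param data_name CIF data block name.
#' @return Invisibly, the lines written.
#' @export
write_cif_cell <- function(cell, path = NULL, data_name = "cell") {
  lines <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a     %.6f", cell$a),
    sprintf("_cell_length_b     %.6f", cell$b),
    sprintf("_cell_length_c     %.6f", cell$c),
    sprintf("_cell_angle_alpha  %.6f", cell$alpha),
    sprintf("_cell_angle_beta   %.6f", cell$beta),
    sprintf("_cell_angle_gamma  %.6f", cell$gamma)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
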