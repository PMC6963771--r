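# The N x 3M ensemble coordinate matrix: one row per structure, columns the
# concatenated (x, y, z) of each shared atom in canonical key order.

#' Build the ensemble coordinate matrix
#'
#' Arranges a superposed ensemble as a numeric matrix with one row per
#' structure and `3 * length(atom_keys)` columns (x, y, z per atom, atoms in
#' canonical order).  With far fewer structures than columns this matrix is
#' degenerate — its empirical covariance cannot be full rank — which is the
#' regime the projection methods in this package are built for.
#'
#' @param structures List of `ca_structure` objects (at least 2), already
#'   superposed.
#' @param atom_keys Character vector of shared atom keys; defaults to
#'   [common_atom_set()].
#' @return A `coord_matrix`: numeric matrix with row names = entry ids,
#'   column names `"chain:resno:icode|x"` etc., and attribute `atom_keys`.
#' @export
build_matrix <- function(structures, atom_keys = NULL) {
  if (length(structures) < 2L)
    stop_ep("need at least 2 structures to build a matrix")
  if (is.null(atom_keys)) atom_keys <- common_atom_set(structures)
  ids <- vapply(structures, function(s) s$entry_id, "")
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  m <- t(vapply(structures, function(s) {
    as.vector(t(s$xyz[match_keys(s, atom_keys), , drop = FALSE]))
  }, numeric(3L * length(atom_keys))))
  rownames(m) <- ids
  colnames(m) <- paste(rep(atom_keys, each = 3L), c("x", "y", "z"), sep = "|")
  structure(m, atom_keys = atom_keys, class = c("coord_matrix", "matrix", "array"))
}

#' @export
print.coord_matrix <- function(x, ...) {
  cat("Ensemble coordinate matrix: ", nrow(x), " structures x ", ncol(x),
      " coordinates (", length(attr(x, "atom_keys")), " atoms)\n", sep = "")
  invisible(x)
}

#' Write / read a coordinate matrix as tab-separated text
#'
#' The first line is a header (`entry_id` then one column per coordinate,
#' named `"chain:resno:icode|axis"`); each following line is an entry id and
#' 3M coordinates printed with 6 decimals, so a write/read round trip is
#' lossless to 1e-6 Angstrom.
#'
#' @param m A `coord_matrix` (or plain numeric matrix with row/col names).
#' @param path File path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   `coord_matrix`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c("entry_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.6f", m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_ep("matrix file ", path, " has no data rows")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L || header[[1L]] != "entry_id")
    stop_ep("malformed header in ", path,
            ": expected 'entry_id' followed by coordinate columns")
  d <- length(header) - 1L
  if (d %% 3L != 0L)
    stop_ep("malformed header in ", path, ": ", d,
            " coordinate columns is not a multiple of 3")
  ids <- character(length(lines) - 1L)
  m <- matrix(NA_real_, length(lines) - 1L, d)
  for (i in seq_along(ids)) {
    cells <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != d + 1L)
      stop_ep("row ", i, " of ", path, " has ", length(cells) - 1L,
              " values, expected ", d)
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(vals))
      stop_ep("non-numeric value at row ", i, " ('", cells[[1L]], "'), column ",
              which(is.na(vals))[1L], " ('", header[which(is.na(vals))[1L] + 1L],
              "') of ", path)
    ids[i] <- cells[[1L]]
    m[i, ] <- vals
  }
  if (anyDuplicated(ids))
    stop_ep("duplicate entry ids in ", path)
  rownames(m) <- ids
  colnames(m) <- header[-1L]
  atom_keys <- unique(sub("\\|[xyz]$", "", header[-1L]))
  if (length(atom_keys) * 3L != d)
    stop_ep("malformed coordinate column names in ", path)
  structure(m, atom_keys = atom_keys, class = c("coord_matrix", "matrix", "array"))
}
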