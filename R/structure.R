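#' Alpha-carbon structure objects
#'
#' A `ca_structure` is the package's in-memory representation of one PDB
#' entry reduced to its alpha-carbon (C-alpha) trace: an entry identifier
#' plus an ordered set of labeled atoms.  Atom identity is the triple
#' (chain id, residue number, insertion code); the residue name is
#' deliberately not part of the key, so mutant or variant entries align by
#' sequence position.  Atoms are kept in canonical order: lexicographic in
#' (chain, residue number, insertion code).
#'
#' @param entry_id Character scalar naming the entry (e.g. a PDB id or file
#'   stem).
#' @param chain Character vector of chain identifiers, one per atom.
#' @param resno Integer vector of residue sequence numbers.
#' @param icode Character vector of insertion codes (`""` when absent).
#' @param xyz Numeric matrix with one row per atom and columns x, y, z, in
#'   Angstrom.
#'
#' @return An object of class `ca_structure`: a list with elements
#'   `entry_id`, `keys` (data frame with columns `chain`, `resno`, `icode`)
#'   and `xyz` (n x 3 coordinate matrix), atoms in canonical order.
#' @export
ca_structure <- function(entry_id, chain, resno, icode, xyz) {
  stopifnot(is.character(entry_id), length(entry_id) == 1L)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  if (ncol(xyz) != 3L)
    stop_ep("'xyz' must have three columns (x, y, z)")
  if (length(chain) != n || length(resno) != n || length(icode) != n)
    stop_ep("atom label vectors and coordinate rows must have equal length")
  if (n < 3L)
    stop_ep("a structure needs at least 3 atoms, got ", n)
  if (!all(is.finite(xyz)))
    stop_ep("non-finite coordinates in structure '", entry_id, "'")
  keys <- data.frame(chain = as.character(chain),
                     resno = as.integer(resno),
                     icode = as.character(icode),
                     stringsAsFactors = FALSE)
  ks <- atom_key_strings(keys)
  if (anyDuplicated(ks))
    stop_ep("duplicate atom key(s) in structure '", entry_id, "': ",
            paste(unique(ks[duplicated(ks)]), collapse = ", "))
  ord <- order(keys$chain, keys$resno, keys$icode, method = "radix")
  structure(list(entry_id = entry_id,
                 keys = keys[ord, , drop = FALSE],
                 xyz = xyz[ord, , drop = FALSE]),
            class = "ca_structure")
}

# Canonical text form of an atom key: "chain:resno:icode".
atom_key_strings <- function(keys) {
  paste(keys$chain, keys$resno, keys$icode, sep = ":")
}

parse_atom_keys <- function(strings) {
  parts <- strsplit(strings, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad))
    stop_ep("malformed atom key(s): ", paste(strings[bad], collapse = ", "))
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             icode = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", ""),
             stringsAsFactors = FALSE)
}

#' @export
print.ca_structure <- function(x, ...) {
  cat("C-alpha structure '", x$entry_id, "': ", nrow(x$xyz), " atoms, chains ",
      paste(unique(x$keys$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param x A `ca_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$xyz)

# Row indices of `keys` (canonical key-string vector) within structure `s`;
# errors if any key is missing.
match_keys <- function(s, key_strings) {
  idx <- match(key_strings, atom_key_strings(s$keys))
  if (anyNA(idx))
    stop_ep("structure '", s$entry_id, "' is missing atom key(s): ",
            paste(utils::head(key_strings[is.na(idx)], 5L), collapse = ", "))
  idx
}

#' Atom keys shared by every structure in an ensemble
#'
#' Intersects the atom-key sets of all structures.  The result, in canonical
#' (chain, residue number, insertion code) order, defines the columns of the
#' ensemble coordinate matrix; a typical curated ensemble of the same protein
#' retains several hundred shared C-alpha positions.
#'
#' @param structures List of `ca_structure` objects (at least two).
#' @return Character vector of shared atom keys (`"chain:resno:icode"`) in
#'   canonical order.
#' @export
common_atom_set <- function(structures) {
  if (length(structures) < 2L)
    stop_ep("need at least 2 structures, got ", length(structures))
  keep <- atom_key_strings(structures[[1L]]$keys)
  for (s in structures[-1L]) {
    keep <- intersect(keep, atom_key_strings(s$keys))
    if (length(keep) == 0L)
      stop_ep("no atom keys shared by all structures; intersection became ",
              "empty at structure '", s$entry_id, "'")
  }
  k <- parse_atom_keys(keep)
  keep[order(k$chain, k$resno, k$icode, method = "radix")]
}
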