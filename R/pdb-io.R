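# PDB ATOM-record reader and writer (fixed columns per wwPDB format v3.3).
# Only the C-alpha trace of the first MODEL is consumed; no R PDB parser is
# available in the dependency set, and the subset of the format needed here
# (ATOM records, fixed columns) is small enough to read directly.

pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Read the alpha-carbon trace of a PDB file
#'
#' Parses ATOM records (wwPDB v3.3 fixed columns) and keeps atoms named
#' `CA` from the first MODEL.  Alternate locations of the same C-alpha are
#' resolved according to `altloc_policy`; the strict `"reject"` mode mirrors
#' curation rules that exclude entries with multiple coordinates for the
#' same alpha-carbon.
#'
#' @param pdb_path Path to a PDB-format file.
#' @param chain_filter Optional character vector; when given, only atoms on
#'   these chains are kept.
#' @param altloc_policy One of `"highest_occupancy"` (default: keep the
#'   alternate location with the largest occupancy, ties broken by altLoc
#'   letter ascending), `"take_first"` (first record wins) or `"reject"`
#'   (any C-alpha with multiple alternate locations aborts the read).
#' @return A [ca_structure] whose `entry_id` is the file stem.
#' @export
read_calpha <- function(pdb_path,
                        chain_filter = NULL,
                        altloc_policy = c("highest_occupancy", "take_first", "reject")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(pdb_path))
    stop_ep("PDB file not found: ", pdb_path)
  lines <- readLines(pdb_path, warn = FALSE)

  # first MODEL only: truncate at the first ENDMDL
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  atom <- lines[startsWith(lines, "ATOM")]
  name <- trimws(pdb_field(atom, 13L, 16L))
  atom <- atom[name == "CA"]
  if (length(atom) == 0L)
    stop_ep("no C-alpha ATOM records in ", pdb_path)

  rec <- data.frame(
    altloc = pdb_field(atom, 17L, 17L),
    chain  = pdb_field(atom, 22L, 22L),
    resno  = as.integer(pdb_field(atom, 23L, 26L)),
    icode  = trimws(pdb_field(atom, 27L, 27L)),
    x = as.numeric(pdb_field(atom, 31L, 38L)),
    y = as.numeric(pdb_field(atom, 39L, 46L)),
    z = as.numeric(pdb_field(atom, 47L, 54L)),
    occ = suppressWarnings(as.numeric(pdb_field(atom, 55L, 60L))),
    stringsAsFactors = FALSE)
  rec$occ[is.na(rec$occ)] <- 1
  if (anyNA(rec[c("resno", "x", "y", "z")]))
    stop_ep("unparsable ATOM record(s) in ", pdb_path)

  if (!is.null(chain_filter))
    rec <- rec[rec$chain %in% chain_filter, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_ep("no C-alpha atoms left after chain filter in ", pdb_path)

  key <- paste(rec$chain, rec$resno, rec$icode, sep = ":")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    if (altloc_policy == "reject")
      stop_ep("alternate locations for C-alpha atom(s) ",
              paste(utils::head(dup_keys, 5L), collapse = ", "),
              " in ", pdb_path, " (altloc_policy = \"reject\")")
    keep <- logical(nrow(rec))
    for (grp in split(seq_len(nrow(rec)), key)) {
      if (length(grp) == 1L) { keep[grp] <- TRUE; next }
      if (altloc_policy == "take_first") {
        keep[grp[1L]] <- TRUE
      } else {                       # highest_occupancy, ties by altLoc letter
        g <- grp[order(-rec$occ[grp], rec$altloc[grp], method = "radix")]
        keep[g[1L]] <- TRUE
      }
    }
    rec <- rec[keep, , drop = FALSE]
  }

  ca_structure(entry_id = sub("\\.[^.]*$", "", basename(pdb_path)),
               chain = rec$chain, resno = rec$resno, icode = rec$icode,
               xyz = cbind(rec$x, rec$y, rec$z))
}

#' Write a structure as a PDB file
#'
#' Emits wwPDB-conformant ATOM records (atom name `CA`, residue `GLY`,
#' occupancy 1.00) with `TER` after each chain and a final `END`.
#' Coordinates survive a write/read round trip to 3 decimal places, the
#' precision of the format.
#'
#' @param x A [ca_structure].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "ca_structure"))
  n <- nrow(x$xyz)
  if (n > 99999L)
    stop_ep("PDB serial-number field cannot hold ", n, " atoms")
  if (any(abs(x$xyz) >= 10000))
    stop_ep("coordinate magnitude exceeds the %8.3f PDB field")
  icode <- ifelse(x$keys$icode == "", " ", substr(x$keys$icode, 1L, 1L))
  rec <- sprintf("ATOM  %5d  CA  GLY %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(n), x$keys$chain, x$keys$resno, icode,
                 x$xyz[, 1L], x$xyz[, 2L], x$xyz[, 3L], 1, 0, "C")
  # TER after the last atom of each chain
  last_of_chain <- cumsum(rle(x$keys$chain)$lengths)
  out <- character(0)
  prev <- 0L
  for (i in last_of_chain) {
    out <- c(out, rec[(prev + 1L):i], "TER")
    prev <- i
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
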