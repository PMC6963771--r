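# Rigid-body ensemble superposition (Kabsch least-squares fitting).

# Optimal proper rotation R (det +1, no reflection) minimizing
# ||(P - cP) R - (Q - cQ)||_F for row-vector coordinate matrices.
kabsch_rotation <- function(Pc, Qc) {
  H <- crossprod(Pc, Qc)             # 3x3
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1                 # degenerate (rank-deficient) case
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Apply the rigid fit of `s` (on rows `idx`) onto reference coords `ref`
# (same atom subset) to ALL atoms of `s`.
fit_structure <- function(s, idx, ref) {
  P <- s$xyz[idx, , drop = FALSE]
  cP <- colMeans(P)
  cQ <- colMeans(ref)
  R <- kabsch_rotation(sweep(P, 2L, cP), sweep(ref, 2L, cQ))
  s$xyz <- sweep(sweep(s$xyz, 2L, cP) %*% R, 2L, cQ, `+`)
  s
}

#' Root-mean-square deviation between two structures
#'
#' Plain coordinate RMSD over a shared atom set, in Angstrom, computed on
#' the structures as given (no fitting is performed here).
#'
#' @param a,b `ca_structure` objects.
#' @param atom_keys Character vector of shared atom keys; defaults to the
#'   intersection of the two structures' keys.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, atom_keys = NULL) {
  if (is.null(atom_keys)) atom_keys <- common_atom_set(list(a, b))
  d <- a$xyz[match_keys(a, atom_keys), , drop = FALSE] -
       b$xyz[match_keys(b, atom_keys), , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Superpose an ensemble of structures
#'
#' Rigid-body (rotation + translation, determinant +1, never a reflection)
#' least-squares superposition of every structure onto a common reference
#' frame, fitting on the shared atom set `atom_keys` but transforming all
#' atoms.
#'
#' With `reference = "iterative_mean"` (default) the ensemble is fitted to
#' the first structure, the mean structure is recomputed, and fitting is
#' repeated until the mean moves less than `tol` Angstrom (RMSD) or
#' `max_iter` rounds have run; the converged frame is then canonicalized by
#' rotating the whole ensemble so the mean structure sits on its own
#' principal axes.  This canonicalization makes the output frame — and hence
#' all downstream projections — invariant under any global rigid motion
#' applied to the input ensemble.  With `reference = "first"` the frame of
#' the first structure is kept as-is (so superposing a structure onto itself
#' is the identity).
#'
#' @param structures List of `ca_structure` objects, each containing every
#'   key in `atom_keys`.
#' @param atom_keys Character vector of shared atom keys (at least 3);
#'   defaults to [common_atom_set()] of the ensemble.
#' @param reference `"iterative_mean"` or `"first"`.
#' @param tol Convergence tolerance on the mean-structure shift, Angstrom.
#' @param max_iter Iteration cap for the mean-reference loop.
#' @return List of superposed `ca_structure` objects, same order.
#' @export
superpose_ensemble <- function(structures, atom_keys = NULL,
                               reference = c("iterative_mean", "first"),
                               tol = 1e-6, max_iter = 50L) {
  reference <- match.arg(reference)
  stopifnot(length(structures) >= 1L)
  if (is.null(atom_keys)) {
    atom_keys <- if (length(structures) >= 2L) common_atom_set(structures)
                 else atom_key_strings(structures[[1L]]$keys)
  }
  if (length(atom_keys) < 3L)
    stop_ep("superposition is underdetermined with ", length(atom_keys),
            " shared atoms (need >= 3)")
  idx <- lapply(structures, match_keys, key_strings = atom_keys)

  ref <- structures[[1L]]$xyz[idx[[1L]], , drop = FALSE]
  fitted <- structures
  if (reference == "first") {
    for (i in seq_along(fitted))
      fitted[[i]] <- fit_structure(fitted[[i]], idx[[i]], ref)
    return(fitted)
  }

  for (iter in seq_len(max_iter)) {
    for (i in seq_along(fitted))
      fitted[[i]] <- fit_structure(fitted[[i]], idx[[i]], ref)
    new_ref <- Reduce(`+`, Map(function(s, ix) s$xyz[ix, , drop = FALSE],
                               fitted, idx)) / length(fitted)
    shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) break
  }
  canonicalize_frame(fitted, ref)
}

# Rotate/translate the whole ensemble so the (centered) mean structure lies
# on its principal axes.  Axis signs must come from structure-intrinsic
# quantities (not ambient components, which change under a global rotation):
# each of the two leading axes is oriented so the sequence-weighted dipole
# of the mean structure along it is positive (skewness as fallback), and
# axis 3 completes a right-handed frame.  Purely a relabeling of the common
# frame; all pairwise geometry is untouched.
canonicalize_frame <- function(fitted, mean_coords) {
  ctr <- colMeans(mean_coords)
  C <- sweep(mean_coords, 2L, ctr)
  ev <- eigen(crossprod(C) / nrow(C), symmetric = TRUE)
  V <- ev$vectors[, 1:2, drop = FALSE]
  w <- seq_len(nrow(C)) - (nrow(C) + 1) / 2
  proj <- C %*% V
  for (j in 1:2) {
    orient <- sum(w * proj[, j])
    if (abs(orient) < 1e-9) orient <- sum(proj[, j]^3)
    if (orient < 0) V[, j] <- -V[, j]
  }
  v3 <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
          V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
          V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  R <- cbind(V, v3)
  lapply(fitted, function(s) {
    s$xyz <- sweep(s$xyz, 2L, ctr) %*% R
    s
  })
}

#' Mean structure of a superposed ensemble
#'
#' Averages coordinates over structures on a shared atom set.  Meaningful
#' only after [superpose_ensemble()].
#'
#' @param structures List of superposed `ca_structure` objects.
#' @param atom_keys Shared atom keys; defaults to the common set.
#' @return A `ca_structure` with entry id `"mean"`.
#' @export
mean_structure <- function(structures, atom_keys = NULL) {
  if (is.null(atom_keys)) atom_keys <- common_atom_set(structures)
  xyz <- Reduce(`+`, lapply(structures, function(s)
    s$xyz[match_keys(s, atom_keys), , drop = FALSE])) / length(structures)
  k <- parse_atom_keys(atom_keys)
  ca_structure("mean", k$chain, k$resno, k$icode, xyz)
}
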