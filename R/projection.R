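# Standardization, covariance/correlation construction, eigendecomposition,
# truncated-SVD PCA, and random-matrix projection.
#
# All first and second moments use divisor-N (population) statistics,
# matching the ensemble-average convention < . > under which the correlation
# matrix of standardized data is exactly X'X / N with unit diagonal.

#' Column-standardize a coordinate matrix
#'
#' Centers every column to mean zero and scales to unit standard deviation
#' (divisor N).  Standardization puts all coordinate degrees of freedom on a
#' common dimensionless scale before projection, so that the correlation —
#' not the covariance — structure drives the embedding.
#'
#' @param m Numeric matrix (typically a `coord_matrix`), N rows
#'   (structures) x D columns (coordinates), N >= 2.
#' @return A `standardized_matrix`: list with `values` (N x D), `center`
#'   (column means) and `scale` (column divisor-N standard deviations).
#' @export
standardize <- function(m) {
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  if (n < 2L) stop_ep("standardization needs at least 2 rows")
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  sdev <- sqrt(colMeans(ctr^2))
  zero <- sdev <= 1e-12
  if (any(zero)) {
    nm <- colnames(m)[zero]
    stop_ep("zero-variance column(s): ",
            paste(utils::head(if (is.null(nm)) which(zero) else nm, 5L),
                  collapse = ", "),
            if (sum(zero) > 5L) sprintf(" (and %d more)", sum(zero) - 5L))
  }
  structure(list(values = sweep(ctr, 2L, sdev, `/`),
                 center = mu, scale = sdev),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat("Standardized matrix: ", nrow(x$values), " x ", ncol(x$values),
      " (columns mean 0, sd 1, divisor N)\n", sep = "")
  invisible(x)
}

#' Covariance matrix (divisor N)
#'
#' The D x D matrix chi_ij = < (x_i - <x_i>)(x_j - <x_j>) > with the average
#' taken over all conformations (rows).
#'
#' @param m Numeric N x D matrix, N >= 2.
#' @return Symmetric D x D covariance matrix.
#' @export
covariance_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 2L) stop_ep("covariance needs at least 2 rows")
  ctr <- sweep(m, 2L, colMeans(m))
  cv <- crossprod(ctr) / nrow(m)
  (cv + t(cv)) / 2
}

#' Correlation matrix from a covariance matrix
#'
#' P_ij = chi_ij / sqrt(chi_ii * chi_jj); unit diagonal, entries clamped to
#' `[-1, 1]` against rounding.
#'
#' @param cov Symmetric covariance matrix with strictly positive diagonal.
#' @return Symmetric correlation matrix.
#' @export
correlation_matrix <- function(cov) {
  d <- diag(cov)
  if (any(d <= 0))
    stop_ep("covariance diagonal must be strictly positive; zero/negative at ",
            paste(utils::head(which(d <= 0), 5L), collapse = ", "))
  p <- cov / sqrt(outer(d, d))
  p[p > 1] <- 1
  p[p < -1] <- -1
  diag(p) <- 1
  (p + t(p)) / 2
}

#' Eigendecomposition of a symmetric matrix
#'
#' Diagonalizes R' P R = Lambda with eigenvalues in descending order and a
#' deterministic sign convention (each eigenvector's largest-magnitude
#' component is positive).  Input asymmetric beyond `1e-8` is rejected;
#' smaller asymmetry is symmetrized as (A + A') / 2.
#'
#' @param a Square numeric matrix, symmetric to 1e-8.
#' @return List with `values` (descending) and `vectors` (orthonormal
#'   columns, paired with `values`).
#' @export
eigendecompose <- function(a) {
  a <- unclass(as.matrix(a))
  if (nrow(a) != ncol(a)) stop_ep("matrix is not square")
  if (max(abs(a - t(a))) > 1e-8)
    stop_ep("matrix is not symmetric (max asymmetry ",
            format(max(abs(a - t(a)))), " > 1e-8)")
  e <- eigen((a + t(a)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = fix_column_signs(e$vectors))
}

new_projection_result <- function(scores, basis, spectrum, method, seed, ids) {
  colnames(scores) <- paste0("component_", seq_len(ncol(scores)))
  rownames(scores) <- ids
  structure(list(scores = scores, basis = basis, spectrum = spectrum,
                 method = method, seed = seed, k = ncol(scores)),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("Projection (", x$method, "): ", nrow(x$scores), " structures, k = ",
      x$k, if (!is.na(x$seed)) paste0(", seed = ", x$seed), "\n",
      "spectrum: ", paste(signif(x$spectrum, 4L), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Principal components by truncated SVD
#'
#' Estimates the leading principal components of a degenerate (N << D)
#' standardized matrix by truncated singular value decomposition, avoiding
#' the explicit D x D correlation matrix.  The basis consists of the top-k
#' right singular vectors; scores are the data projected onto it, and the
#' spectrum holds the corresponding correlation-matrix eigenvalues
#' (squared singular values / N).  Equivalent, up to sign, to
#' diagonalizing the full correlation matrix and projecting onto its
#' leading eigenvectors.
#'
#' @param std A `standardized_matrix` (or plain numeric matrix, used as-is).
#' @param k Number of components, `1 <= k <= min(N - 1, D)` (default 2; all
#'   the package's figures are two-dimensional projections).
#' @return A `projection_result` with `method = "pca_tsvd"`.
#' @export
pca_project <- function(std, k = 2L) {
  x <- if (inherits(std, "standardized_matrix")) std$values else unclass(as.matrix(std))
  n <- nrow(x); d <- ncol(x)
  kmax <- min(n - 1L, d)
  if (!is_count(k) || k < 1L || k > kmax)
    stop_ep("k must be in 1..", kmax, " (min(N-1, D)), got ", k)
  s <- svd(x, nu = 0L, nv = k)
  basis <- fix_column_signs(s$v[, seq_len(k), drop = FALSE])
  new_projection_result(scores = x %*% basis, basis = basis,
                        spectrum = s$d[seq_len(k)]^2 / n,
                        method = "pca_tsvd", seed = NA_integer_,
                        ids = rownames(x))
}

#' Symmetric Gaussian random matrix
#'
#' Draws a D x D symmetric matrix with independent standard-normal entries
#' on and above the diagonal, mirrored below — the Gaussian orthogonal
#' ensemble up to scaling.  Its eigenbasis is rotation-invariant, so the
#' leading-k eigenvectors form a uniformly random orthonormal k-frame: the
#' substitute basis used by [random_project()].  Reproducible: the same
#' `(dimension, seed)` always regenerates the identical matrix, and the
#' caller's RNG state is left untouched.
#'
#' @param dimension Matrix dimension D (>= 2).
#' @param seed Integer seed.
#' @param ensemble Random-matrix ensemble; only `"gaussian_symmetric"`.
#' @return D x D symmetric numeric matrix.
#' @export
random_symmetric_matrix <- function(dimension, seed,
                                    ensemble = "gaussian_symmetric") {
  ensemble <- match.arg(ensemble)
  if (!is_count(dimension) || dimension < 2L)
    stop_ep("dimension must be an integer >= 2")
  d <- as.integer(dimension)
  with_preserved_rng(seed, {
    m <- matrix(0, d, d)
    up <- upper.tri(m, diag = TRUE)
    m[up] <- stats::rnorm(sum(up))
    m + t(m) - diag(diag(m))
  })
}

#' Random projection via a symmetric random matrix
#'
#' The random-projection track works exactly like correlation-matrix PCA
#' except that the D x D correlation matrix is replaced by a symmetric
#' Gaussian random matrix of the same dimension: that matrix is
#' diagonalized and the standardized data are projected onto the
#' eigenvectors of its k largest eigenvalues.  Because the ensemble's
#' eigenbasis is rotation-invariant, this projects onto a uniformly random
#' orthonormal k-frame — structure visible in such an uninformed embedding
#' cannot be an artifact of variance maximization, which is what makes it a
#' useful cross-check on PCA clusters.  Deterministic given
#' `(data, seed, k)`.
#'
#' @param std A `standardized_matrix` (or plain numeric matrix).
#' @param seed Integer seed for the random matrix.
#' @param k Number of components, `1 <= k <= D` (default 2).
#' @return A `projection_result` with `method = "random_projection"`.
#' @export
random_project <- function(std, seed, k = 2L) {
  x <- if (inherits(std, "standardized_matrix")) std$values else unclass(as.matrix(std))
  d <- ncol(x)
  if (!is_count(k) || k < 1L || k > d)
    stop_ep("k must be in 1..", d, ", got ", k)
  m <- random_symmetric_matrix(d, seed)
  top <- top_eigen_symmetric(m, as.integer(k))
  basis <- fix_column_signs(top$vectors)
  new_projection_result(scores = x %*% basis, basis = basis,
                        spectrum = top$values,
                        method = "random_projection", seed = as.integer(seed),
                        ids = rownames(x))
}

# Leading-k eigenpairs of a symmetric matrix.  Uses a LAPACK dsyevr range
# query (compiled code) so k << D costs one tridiagonalization instead of a
# full eigendecomposition; falls back to eigen() for small problems.
top_eigen_symmetric <- function(m, k) {
  d <- nrow(m)
  if (d <= 64L || k > d %/% 2L) {
    e <- eigen(m, symmetric = TRUE)
    return(list(values = e$values[seq_len(k)],
                vectors = e$vectors[, seq_len(k), drop = FALSE]))
  }
  .Call(C_top_eigen_sym, m, as.integer(k))
}
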