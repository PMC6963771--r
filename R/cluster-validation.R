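# Cluster detection in 2-D embeddings, cross-method agreement / validation
# verdict, chi-square confidence ellipses and Mahalanobis outlier flagging.

new_cluster_assignment <- function(labels, method, parameters) {
  labels <- as.integer(labels)
  pos <- sort(unique(labels[labels >= 0L]))
  if (length(pos) && !identical(pos, seq_along(pos) - 1L))
    stop_ep("cluster labels must cover a contiguous set 0..m-1 (plus -1)")
  structure(list(labels = labels, method = method, parameters = parameters),
            class = "cluster_assignment")
}

#' Number of clusters in an assignment (outliers excluded)
#' @param a A `cluster_assignment`.
#' @return Integer count of non-outlier clusters.
#' @export
n_clusters <- function(a) length(unique(a$labels[a$labels >= 0L]))

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment (", x$method, "): ", n_clusters(x), " cluster(s), ",
      sum(x$labels == -1L), " outlier(s), N = ", length(x$labels), "\n", sep = "")
  invisible(x)
}

# Mean silhouette width of a labeling (>= 2 clusters) from a distance matrix.
mean_silhouette <- function(labels, dmat) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(dmat[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(dmat[i, labels == cl]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Detect clusters in a 2-D embedding
#'
#' Two detectors are available.  `"density"` (default, parameter-free in k):
#' points closer than a neighborhood radius are linked, connected components
#' are candidate clusters, and components smaller than `min_size` are
#' labeled `-1` (outliers).  The radius is `radius_factor` times the median
#' distance to the `(min_size - 1)`-th nearest neighbor — the distance at
#' which a typical point has enough neighbors to seed a minimum-size
#' cluster (the plain nearest-neighbor spacing makes single-linkage
#' components fragment even for clean Gaussian clouds).
#' `"kmeans_silhouette"`: k-means for k = 2..`k_max`, the k with the best
#' mean silhouette wins, and k = 1 is declared when that best silhouette is
#' below `silhouette_min`; `fixed_k` bypasses the selection (useful to force
#' a variance-maximizing split and test whether the other embedding
#' confirms it).  Cluster ids are renumbered 0..m-1 by decreasing size
#' (ties by first member).
#'
#' Boundary behavior, deterministic by construction: points that all
#' coincide form one cluster; 3 mutually distant points with `min_size = 3`
#' form one cluster (the neighborhood radius is derived from their own
#' spacing, so they link).
#'
#' @param scores N x 2 numeric matrix (an embedding), N >= 3.
#' @param method `"density"` or `"kmeans_silhouette"`.
#' @param radius_factor Link-radius multiplier c (default 3).
#' @param min_size Minimum cluster size (default 3).
#' @param k_max Largest k tried by the silhouette scan (default 5).
#' @param silhouette_min Mean-silhouette floor below which k = 1 is declared
#'   (default 0.5).
#' @param fixed_k Optional fixed number of k-means clusters.
#' @param seed Seed for the k-means starts (default 1); the density detector
#'   is fully deterministic.
#' @return A `cluster_assignment` with integer labels (`-1` = outlier).
#' @export
detect_clusters <- function(scores,
                            method = c("density", "kmeans_silhouette"),
                            radius_factor = 3, min_size = 3L,
                            k_max = 5L, silhouette_min = 0.5,
                            fixed_k = NULL, seed = 1L) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < min_size)
    stop_ep("need at least ", min_size, " points, got ", n)
  params <- list(radius_factor = radius_factor, min_size = min_size,
                 k_max = k_max, silhouette_min = silhouette_min,
                 fixed_k = fixed_k, seed = seed)

  if (method == "density") {
    dmat <- as.matrix(stats::dist(scores))
    diag(dmat) <- Inf
    # neighborhood scale: distance at which a typical point has min_size - 1
    # neighbors (enough to seed a minimum-size cluster); plain 1st-NN spacing
    # fragments moderately sized Gaussian clouds at c = 3
    k_nn <- min(min_size - 1L, n - 1L)
    radius <- radius_factor *
      stats::median(apply(dmat, 1L, function(r) sort(r)[k_nn]))
    diag(dmat) <- 0
    # connected components at threshold `radius` = single-linkage cut
    comp <- if (radius <= 0) {
      match(apply(scores, 1L, paste, collapse = "\r"),
            unique(apply(scores, 1L, paste, collapse = "\r")))
    } else {
      stats::cutree(stats::hclust(stats::as.dist(dmat), method = "single"),
                    h = radius)
    }
    sizes <- table(comp)
    labels <- rep(-1L, n)
    big <- as.integer(names(sizes)[sizes >= min_size])
    for (cl in big) labels[comp == cl] <- 0L   # placeholder, renumbered below
    raw <- ifelse(comp %in% big, comp, -1L)
  } else {
    k_req <- if (!is.null(fixed_k)) fixed_k else {
      dmat <- as.matrix(stats::dist(scores))
      ks <- 2:min(k_max, n - 1L)
      sil <- vapply(ks, function(k) {
        cl <- with_preserved_rng(seed, stats::kmeans(scores, centers = k,
                                                     nstart = 25L, iter.max = 100L))
        mean_silhouette(cl$cluster, dmat)
      }, 0)
      if (max(sil) < silhouette_min) 1L else ks[which.max(sil)]
    }
    raw <- if (k_req == 1L) rep(1L, n)
           else with_preserved_rng(seed, stats::kmeans(scores, centers = k_req,
                                                       nstart = 25L,
                                                       iter.max = 100L))$cluster
  }
  new_cluster_assignment(renumber_labels(raw), method, params)
}

# Map raw component ids (with -1 outliers) to 0..m-1 by decreasing cluster
# size, ties broken by first-member index.
renumber_labels <- function(raw) {
  labels <- rep(-1L, length(raw))
  ids <- unique(raw[raw != -1L])
  if (length(ids)) {
    size <- vapply(ids, function(i) sum(raw == i), 0L)
    first <- vapply(ids, function(i) which(raw == i)[1L], 0L)
    ids <- ids[order(-size, first)]
    for (j in seq_along(ids)) labels[raw == ids[j]] <- j - 1L
  }
  labels
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items: 1 for identical partitions (up to label permutation), about 0
#' for independent ones.  Two single-cluster partitions are defined to agree
#' perfectly (index 1).
#'
#' @param a,b Integer label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop_ep("label vectors differ in length (", length(a), " vs ", length(b), ")")
  n <- length(a)
  if (n < 2L) stop_ep("need at least 2 items")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2L))
  sum_a <- sum(choose(rowSums(tab), 2L))
  sum_b <- sum(choose(colSums(tab), 2L))
  expected <- sum_a * sum_b / choose(n, 2L)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < .Machine$double.eps * max(1, max_idx))
    return(1)                              # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Cross-method cluster agreement and validation verdict
#'
#' Implements the cross-validation rule for two-track embeddings: clusters
#' are `"validated"` only when both methods see the same partition — the
#' adjusted Rand index over points that are non-outliers in both
#' assignments reaches `threshold` AND both methods report the same number
#' of clusters.  A variance-maximizing split that the random projection
#' does not reproduce (different cluster counts) is `"unvalidated"`
#' regardless of the index.
#'
#' @param a,b `cluster_assignment` objects (conventionally PCA and random
#'   projection) over the same N points.
#' @param threshold Agreement threshold (default 0.9).
#' @return A `cluster_report`: list with `assignment_pca`,
#'   `assignment_random`, `agreement`, `n_clusters_pca`,
#'   `n_clusters_random`, `n_compared` and `verdict`
#'   (`"validated"`/`"unvalidated"`).
#' @export
cluster_agreement <- function(a, b, threshold = 0.9) {
  stopifnot(inherits(a, "cluster_assignment"), inherits(b, "cluster_assignment"))
  if (length(a$labels) != length(b$labels))
    stop_ep("assignments cover different numbers of points (",
            length(a$labels), " vs ", length(b$labels), ")")
  keep <- a$labels >= 0L & b$labels >= 0L
  ka <- n_clusters(a); kb <- n_clusters(b)
  agreement <- if (sum(keep) >= 2L)
    adjusted_rand_index(a$labels[keep], b$labels[keep]) else NA_real_
  verdict <- if (!is.na(agreement) && agreement >= threshold && ka == kb)
    "validated" else "unvalidated"
  structure(list(assignment_pca = a, assignment_random = b,
                 agreement = agreement,
                 n_clusters_pca = ka, n_clusters_random = kb,
                 n_compared = sum(keep), threshold = threshold,
                 verdict = verdict),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster cross-validation report\n",
      "  clusters: ", x$n_clusters_pca, " (pca) vs ", x$n_clusters_random,
      " (random projection)\n",
      "  agreement (ARI over ", x$n_compared, " shared non-outliers): ",
      formatC(x$agreement, digits = 3, format = "f"), "\n",
      "  verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Chi-square confidence ellipse of a 2-D point cloud
#'
#' Assuming the projected data are bivariate normal, the squared Mahalanobis
#' distance follows a chi-square distribution with 2 degrees of freedom, so
#' the level-`level` ellipse is centered at the sample mean with semi-axis i
#' equal to `sqrt(lambda_i * qchisq(level, 2))`, where `lambda_i` are the
#' eigenvalues of the 2 x 2 sample covariance; the orientation follows the
#' leading eigenvector.
#'
#' @param points M x 2 numeric matrix, M >= 3, not collinear.
#' @param level Confidence level in (0, 1).
#' @return An `ellipse_spec`: list with `center` (2-vector), `semi_axes`
#'   (descending), `angle` (radians in (-pi/2, pi/2]) and `level`.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 2L)
    stop_ep("need an M x 2 matrix with M >= 3")
  if (!(level > 0 && level < 1)) stop_ep("level must be in (0, 1)")
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(e$values, 1))
    stop_ep("singular covariance (collinear points); no ellipse")
  q <- stats::qchisq(level, df = 2L)
  angle <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L])
  if (angle <= -pi / 2) angle <- angle + pi
  if (angle > pi / 2) angle <- angle - pi
  structure(list(center = colMeans(points),
                 semi_axes = sqrt(e$values * q),
                 angle = angle, level = level),
            class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat("Confidence ellipse (level ", x$level, "): center (",
      paste(signif(x$center, 4L), collapse = ", "), "), semi-axes ",
      paste(signif(x$semi_axes, 4L), collapse = ", "), ", angle ",
      signif(x$angle, 4L), " rad\n", sep = "")
  invisible(x)
}

#' Test points against a confidence ellipse
#'
#' @param spec An `ellipse_spec`.
#' @param points M x 2 numeric matrix.
#' @return Logical vector: is each point inside or on the ellipse?
#' @export
ellipse_contains <- function(spec, points) {
  points <- as.matrix(points)
  rot <- matrix(c(cos(spec$angle), -sin(spec$angle),
                  sin(spec$angle),  cos(spec$angle)), 2L, 2L, byrow = TRUE)
  y <- sweep(points, 2L, spec$center) %*% rot
  (y[, 1L] / spec$semi_axes[1L])^2 + (y[, 2L] / spec$semi_axes[2L])^2 <= 1
}

#' Polygon outline of a confidence ellipse
#'
#' @param spec An `ellipse_spec`.
#' @param n Number of vertices.
#' @return n x 2 matrix of boundary points (closed when plotted with
#'   `polygon()`).
#' @export
ellipse_path <- function(spec, n = 181L) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- cbind(spec$semi_axes[1L] * cos(t), spec$semi_axes[2L] * sin(t))
  rot <- matrix(c(cos(spec$angle), sin(spec$angle),
                  -sin(spec$angle), cos(spec$angle)), 2L, 2L, byrow = TRUE)
  sweep(u %*% rot, 2L, spec$center, `+`)
}

#' Flag outliers by Mahalanobis distance
#'
#' A point is flagged when its squared Mahalanobis distance from the cloud
#' (sample mean/covariance) exceeds the chi-square quantile with 2 degrees
#' of freedom at `level` — i.e. it falls outside the level-`level`
#' confidence ellipse.
#'
#' @param scores N x 2 numeric matrix, N >= 3.
#' @param level Confidence level (default 0.99).
#' @return Logical mask of length N.
#' @export
flag_outliers <- function(scores, level = 0.99) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L || ncol(scores) != 2L)
    stop_ep("need an N x 2 matrix with N >= 3")
  if (!(level > 0 && level <= 1)) stop_ep("level must be in (0, 1]")
  S <- stats::cov(scores)
  if (abs(det(S)) <= .Machine$double.eps * max(abs(S))^2)
    stop_ep("singular covariance; cannot compute Mahalanobis distances")
  md <- stats::mahalanobis(scores, colMeans(scores), S)
  md > stats::qchisq(level, df = 2L)
}
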