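# Two-panel embedding figure: PCA on the left, random projection on the
# right, points colored by cluster (outliers gray) with confidence ellipses.

cluster_palette <- function(m) {
  grDevices::hcl.colors(max(m, 3L), palette = "Dark 3")[seq_len(max(m, 1L))]
}

plot_embedding_panel <- function(proj, assignment, levels, main) {
  scores <- proj$scores
  labels <- assignment$labels
  m <- n_clusters(assignment)
  cols <- rep("grey60", length(labels))
  if (m > 0L) cols[labels >= 0L] <- cluster_palette(m)[labels[labels >= 0L] + 1L]
  graphics::plot(scores[, 1L], scores[, 2L], pch = 21L, bg = cols,
                 col = "black", xlab = "component 1", ylab = "component 2",
                 main = main, asp = 1)
  for (cl in seq_len(m) - 1L) {
    pts <- scores[labels == cl, , drop = FALSE]
    if (nrow(pts) < 3L) next
    for (i in seq_along(levels)) {
      spec <- tryCatch(confidence_ellipse(pts, levels[i]),
                       error = function(e) NULL)
      if (is.null(spec)) next
      path <- ellipse_path(spec)
      graphics::lines(path[, 1L], path[, 2L],
                      col = cluster_palette(m)[cl + 1L],
                      lty = i, lwd = 1.5)
    }
  }
}

#' Two-panel validation figure
#'
#' Scatter plots of the PCA and random-projection embeddings side by side,
#' colored by detected cluster (outliers gray), with per-cluster confidence
#' ellipses at the requested levels.
#'
#' @param proj_pca,proj_random `projection_result` objects (k = 2).
#' @param assignment_pca,assignment_random Matching `cluster_assignment`s.
#' @param file Optional output path ending in `.png` or `.svg`; when `NULL`
#'   the current graphics device is used.
#' @param levels Confidence levels for the ellipses.
#' @return Invisibly, `file` (or `NULL`).
#' @export
plot_validation <- function(proj_pca, proj_random,
                            assignment_pca, assignment_random,
                            file = NULL, levels = c(0.95, 0.99)) {
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 1400L, height = 700L, res = 120L),
           svg = grDevices::svg(file, width = 12, height = 6),
           stop_ep("unsupported figure format '", ext, "' (use .png or .svg)"))
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1L, 2L), mar = c(4.2, 4.2, 2.5, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  plot_embedding_panel(proj_pca, assignment_pca, levels, "PCA (truncated SVD)")
  plot_embedding_panel(proj_random, assignment_random, levels, "Random projection")
  invisible(file)
}
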