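# End-to-end workflow: (simulate | read PDBs) -> superpose -> matrix ->
# standardize -> project (PCA + random projection) -> detect -> validate ->
# ellipses -> manifest.  The pipeline is a pure function of (input files,
# config, seed): one seed field is expanded deterministically per stage.

default_config <- function() {
  list(
    seed = 1L,
    simulate = NULL,          # list(chain_sizes, n_clusters, per_cluster_counts,
                              #      displacement, noise_sigma, rigid_jitter)
    pdb_dir = NULL,           # alternative input: directory of PDB files
    chains = NULL,
    altloc = "highest_occupancy",
    reference = "iterative_mean",
    k = 2L,
    detector = "density",
    detector_pca = list(),    # per-track overrides, e.g. list(method =
    detector_random = list(), #   "kmeans_silhouette", fixed_k = 3)
    threshold = 0.9,
    ellipse_levels = c(0.95, 0.99),
    outlier_level = 0.99,
    make_plot = FALSE
  )
}

# Stage seeds derived from the single config seed; kept below 2^31.
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000000L
  list(simulate = base, random_projection = base + 1L, detect = base + 2L)
}

read_config <- function(config) {
  cfg <- default_config()
  user <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
          else config
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop_ep("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  if (is.null(cfg$simulate) && is.null(cfg$pdb_dir))
    stop_ep("config must provide either 'simulate' or 'pdb_dir'")
  cfg
}

run_detector <- function(scores, cfg, override, seed) {
  args <- c(list(scores = scores,
                 method = cfg$detector,
                 seed = seed),
            override)
  # overrides may replace the method itself
  if (!is.null(override$method)) args$method <- override$method
  args <- args[!duplicated(names(args))]
  do.call(detect_clusters, args)
}

#' Run the full two-track analysis pipeline
#'
#' Executes every stage on either a synthetic ensemble (config field
#' `simulate`) or a directory of PDB files (`pdb_dir`): superposition,
#' coordinate-matrix construction, standardization, truncated-SVD PCA and
#' random projection, cluster detection on both embeddings, the
#' cross-method validation verdict, per-cluster confidence ellipses and
#' outlier flags.  All artifacts (matrix, score tables, report, manifest,
#' optional figure) are written under `out_dir`.
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#'   Fields (all optional except one of `simulate`/`pdb_dir`): `seed`,
#'   `simulate`, `pdb_dir`, `chains`, `altloc`, `reference`, `k`,
#'   `detector`, `detector_pca`, `detector_random`, `threshold`,
#'   `ellipse_levels`, `outlier_level`, `make_plot`.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (named list), invisibly written as
#'   `manifest.json`; re-running from the same config reproduces the score
#'   files bit for bit.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  cfg <- read_config(config)
  seeds <- stage_seeds(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ep("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  true_labels <- NULL
  structures <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- do.call(ensemble_recipe, c(cfg$simulate, list(seed = seeds$simulate)))
      ens <- simulate_ensemble(sim)
      true_labels <- ens$true_labels
      ens$structures
    } else {
      paths <- sort(list.files(cfg$pdb_dir, pattern = "\\.(pdb|ent)$",
                               full.names = TRUE))
      if (!length(paths)) stop_ep("no PDB files in ", cfg$pdb_dir)
      lapply(paths, read_calpha, chain_filter = cfg$chains,
             altloc_policy = cfg$altloc)
    }
  })

  atom_keys <- stage("common_atom_set", common_atom_set(structures))
  structures <- stage("superpose",
                      superpose_ensemble(structures, atom_keys,
                                         reference = cfg$reference))
  mat <- stage("build_matrix", build_matrix(structures, atom_keys))
  write_matrix(mat, file.path(out_dir, "matrix.tsv"))

  std <- stage("standardize", standardize(mat))
  proj_pca <- stage("pca", pca_project(std, k = cfg$k))
  proj_rnd <- stage("random_projection",
                    random_project(std, seed = seeds$random_projection, k = cfg$k))
  write_scores(proj_pca, file.path(out_dir, "scores_pca.tsv"))
  write_scores(proj_rnd, file.path(out_dir, "scores_random.tsv"))

  asg_pca <- stage("detect_pca",
                   run_detector(proj_pca$scores, cfg, cfg$detector_pca, seeds$detect))
  asg_rnd <- stage("detect_random",
                   run_detector(proj_rnd$scores, cfg, cfg$detector_random, seeds$detect))
  report <- stage("validate", cluster_agreement(asg_pca, asg_rnd, cfg$threshold))

  ellipses <- stage("ellipses", cluster_ellipses(proj_pca$scores, asg_pca,
                                                 cfg$ellipse_levels))
  outliers <- stage("outliers", tryCatch(flag_outliers(proj_pca$scores,
                                                       cfg$outlier_level),
                                         error = function(e) NULL))

  report_obj <- list(
    labels_pca = report$assignment_pca$labels,
    labels_random = report$assignment_random$labels,
    agreement = report$agreement,
    n_clusters_pca = report$n_clusters_pca,
    n_clusters_random = report$n_clusters_random,
    verdict = report$verdict,
    outliers_pca_mahalanobis = outliers,
    ellipses = ellipses,
    true_labels = true_labels)
  jsonlite::write_json(report_obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (isTRUE(cfg$make_plot))
    stage("plot", plot_validation(proj_pca, proj_rnd, asg_pca, asg_rnd,
                                  file = file.path(out_dir, "embedding.png"),
                                  levels = cfg$ellipse_levels))

  manifest <- list(
    tool = "ensembleproj",
    version = as.character(utils::packageVersion("ensembleproj")),
    config = cfg,
    seeds = seeds,
    n_structures = nrow(mat),
    n_atoms = length(atom_keys),
    matrix_shape = dim(mat),
    spectrum_pca = proj_pca$spectrum,
    spectrum_random = proj_rnd$spectrum,
    agreement = report$agreement,
    verdict = report$verdict)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

write_scores <- function(proj, path) {
  df <- data.frame(entry_id = rownames(proj$scores), proj$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-cluster confidence ellipses (skipping clusters too small or collinear).
cluster_ellipses <- function(scores, assignment, levels) {
  out <- list()
  for (cl in sort(unique(assignment$labels[assignment$labels >= 0L]))) {
    pts <- scores[assignment$labels == cl, , drop = FALSE]
    if (nrow(pts) < 3L) next
    for (lv in levels) {
      spec <- tryCatch(confidence_ellipse(pts, lv), error = function(e) NULL)
      if (!is.null(spec))
        out[[length(out) + 1L]] <- list(cluster = cl, level = lv,
                                        center = spec$center,
                                        semi_axes = spec$semi_axes,
                                        angle = spec$angle)
    }
  }
  out
}
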