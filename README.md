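# ensembleproj

Two-track dimensionality reduction and cluster validation for protein
structure ensembles.

## The problem

For many well-studied proteins the PDB holds dozens of independently solved
crystal structures. Comparing them can reveal functional conformational
states — but the data matrix is *degenerate*: `N` structures (tens) against
`D = 3M` coordinate degrees of freedom (thousands for a protein with `M`
Cα atoms). The empirical covariance is rank-deficient, and apparent clusters
in a low-dimensional embedding may be artifacts of variance maximization on
under-sampled noise.

`ensembleproj` implements a two-track workflow for this regime:

1. **PCA by truncated SVD.** Each structure is a row of the coordinate
   matrix `X` (Cα coordinates after least-squares rigid-body superposition).
   Columns are standardized, `x_std = (x − μ_x)/σ_x`, so the embedding is
   driven by the correlation matrix `P_ij = χ_ij / √(χ_ii χ_jj)` with
   `χ_ij = ⟨(x_i − ⟨x_i⟩)(x_j − ⟨x_j⟩)⟩` (divisor-`N` ensemble averages).
   The leading eigenvectors of `P` (`RᵀPR = Λ`) are estimated directly from
   the top right singular vectors of the standardized matrix, avoiding the
   explicit `D × D` matrix.
2. **Random projection.** The same procedure with `P` replaced by a
   symmetric Gaussian random matrix of the same dimension (GOE): the data
   are projected onto the eigenvectors of its `k` largest eigenvalues.
   Because the GOE eigenbasis is rotation-invariant, this is a uniformly
   random orthonormal `k`-frame — an embedding that knows nothing about the
   data's variance structure.
3. **Cross-validation rule.** Clusters detected in the two embeddings are
   compared by the adjusted Rand index. Clusters are reported as
   `validated` only when both embeddings show the *same* partition (equal
   cluster counts and ARI ≥ 0.9 over shared non-outliers). A split that
   only PCA produces is flagged `unvalidated` — caution required.
4. **Confidence ellipses and outliers.** Assuming bivariate normal scores,
   the level-`q` ellipse has semi-axes `√(λ_i · χ²₂(q))` from the 2 × 2
   score covariance; points outside the 99% Mahalanobis contour are flagged.

A synthetic-ensemble generator (ideal helical folds, cluster-specific
domain-block displacements, Gaussian thermal noise, rigid-body jitter)
makes the whole pipeline testable without any database access.

## Worked example

```r
library(ensembleproj)

rec <- ensemble_recipe(chain_sizes = 120, n_clusters = 2,
                       per_cluster_counts = c(12, 12),
                       displacement = 6, noise_sigma = 0.1,
                       rigid_jitter = TRUE, seed = 42)
ens <- simulate_ensemble(rec)
#> Labeled synthetic ensemble: 24 structures, 2 cluster(s), 120 atoms, seed 42

keys <- common_atom_set(ens$structures)
sup  <- superpose_ensemble(ens$structures, keys)   # Kabsch, iterative mean
mat  <- build_matrix(sup, keys)
#> Ensemble coordinate matrix: 24 structures x 360 coordinates (120 atoms)

std  <- standardize(mat)
pca  <- pca_project(std, k = 2)
#> Projection (pca_tsvd): 24 structures, k = 2
#> spectrum: 318.8, 3.826
rnd  <- random_project(std, seed = 43, k = 2)
#> Projection (random_projection): 24 structures, k = 2, seed = 43
#> spectrum: 37.34, 36.45

report <- cluster_agreement(detect_clusters(pca$scores),
                            detect_clusters(rnd$scores))
#> Cluster cross-validation report
#>   clusters: 2 (pca) vs 2 (random projection)
#>   agreement (ARI over 24 shared non-outliers): 1.000
#>   verdict: validated
```

Both embeddings recover the two planted conformational basins with ARI = 1
against the ground-truth labels, so the verdict is `validated`. The PCA
spectrum is dominated by its first component (318.8 of 360 total
standardized variance — the inter-cluster axis), while the random
projection's spectrum (37.3, 36.5) is just the edge of the GOE semicircle
and carries no such meaning. Raising `noise_sigma` to 0.2 Å makes the same
split invisible to the random frame: PCA still reports 2 clusters, the
random track reports 1, and the verdict flips to `unvalidated` — exactly
the over-splitting caution the two-track rule exists to raise.

## Command line

```sh
ensembleproj simulate --chains 565 --clusters 2 --count 30,28 \
    --displacement 5 --noise 0.3 --jitter --seed 7 --out-dir fixtures/
ensembleproj build-matrix --pdb-dir fixtures/ --altloc occupancy \
    --reference mean --out matrix.tsv
ensembleproj project --matrix matrix.tsv --method pca --out scores_pca.tsv
ensembleproj project --matrix matrix.tsv --method random --seed 1234 \
    --out scores_rnd.tsv
ensembleproj validate --scores-pca scores_pca.tsv \
    --scores-random scores_rnd.tsv --out report.json
ensembleproj run --config config.json --out-dir run1/   # whole pipeline
```

The wrapper script lives at
`system.file("scripts", "ensembleproj", package = "ensembleproj")`; exit
codes are 0 (ok), 1 (validation failure), 2 (error). `run` writes a
`manifest.json` from which every score file is bit-reproducible.

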