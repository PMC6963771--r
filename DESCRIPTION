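Package: ensembleproj
Title: Two-Track Dimensionality Reduction and Cluster Validation for
    Protein Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Ensembleproj", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exploratory analysis of degenerate protein-structure data sets
    (many fewer crystal structures than coordinate degrees of freedom).
    Reads PDB files, extracts alpha-carbon traces, superposes an ensemble by
    least-squares rigid-body fitting and arranges it as a one-row-per-structure
    coordinate matrix.  Two low-dimensional embeddings are computed from the
    standardized matrix: principal components estimated by truncated singular
    value decomposition, and a random projection obtained by diagonalizing a
    symmetric Gaussian random matrix of the same dimension as the correlation
    matrix.  Clusters detected in the two embeddings are cross-validated
    (clusters are credible only when both methods agree), with chi-square
    confidence ellipses and Mahalanobis outlier flagging.  Includes a
    synthetic-ensemble generator with known cluster structure, thermal noise
    and rigid-body jitter, plus a command-line pipeline with a reproducibility
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
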