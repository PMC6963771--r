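# Internal helpers shared across modules.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards.  All seeded operations in the package go through this so that
# library calls never perturb the user's random stream.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

stop_ep <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Fix eigen/singular-vector sign so each column's largest-magnitude entry is
# positive; makes decompositions comparable across runs and platforms.
fix_column_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}
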