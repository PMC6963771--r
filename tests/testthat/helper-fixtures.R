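# Shared fixtures and independent oracles, all built in code.

# --- PDB text fixtures ------------------------------------------------------

pdb_atom_line <- function(serial, name, altloc, resname, chain, resno, icode,
                          x, y, z, occ = 1, bfac = 0) {
  # name is placed in columns 13-16; C-alpha is " CA "
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resno, icode,
          x, y, z, occ, bfac, "C")
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# minimal 3-residue chain-A fixture
three_residue_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, " N  ", " ", "ALA", "A", 1, " ", 0, 0, 0),
    pdb_atom_line(2, " CA ", " ", "ALA", "A", 1, " ", 1.0, 2.0, 3.0),
    pdb_atom_line(3, " CA ", " ", "GLY", "A", 2, " ", 4.0, 5.0, 6.0),
    pdb_atom_line(4, " O  ", " ", "GLY", "A", 2, " ", 9, 9, 9),
    pdb_atom_line(5, " CA ", " ", "SER", "A", 3, " ", 7.0, 8.0, 9.0)))
}

# fixture with an alternate-location C-alpha at residue 2 (A occ 0.4, B occ 0.6)
altloc_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, " CA ", " ", "ALA", "A", 1, " ", 0, 0, 0),
    pdb_atom_line(2, " CA ", "A", "GLY", "A", 2, " ", 1.0, 1.0, 1.0, occ = 0.4),
    pdb_atom_line(3, " CA ", "B", "GLY", "A", 2, " ", 2.0, 2.0, 2.0, occ = 0.6),
    pdb_atom_line(4, " CA ", " ", "SER", "A", 3, " ", 3.0, 3.0, 3.0)))
}

# --- random structures and rigid motions ------------------------------------

random_structure <- function(n = 12L, entry_id = "rnd", chain = "A") {
  ca_structure(entry_id, rep(chain, n), seq_len(n), rep("", n),
               matrix(stats::rnorm(3L * n, sd = 5), n, 3L))
}

random_rigid <- function() {
  q <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  list(R = R, t = stats::rnorm(3L, sd = 20))
}

apply_rigid <- function(s, motion) {
  s$xyz <- sweep(s$xyz %*% t(motion$R), 2L, motion$t, `+`)
  s
}

# --- independent oracles ----------------------------------------------------

# brute-force adjusted Rand index straight from pair counting (O(n^2)),
# independent of the package's contingency-table implementation
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# full-correlation-matrix PCA oracle: explicit P, eigendecomposition, project
pca_oracle <- function(x_std, k) {
  p <- covariance_matrix(x_std)          # of standardized data = correlation
  e <- eigen((p + t(p)) / 2, symmetric = TRUE)
  basis <- e$vectors[, seq_len(k), drop = FALSE]
  list(scores = x_std %*% basis, values = e$values[seq_len(k)])
}

# semicircle CDF on [-2, 2] (unit-variance scaling)
semicircle_cdf <- function(x) {
  x <- pmin(pmax(x, -2), 2)
  0.5 + x * sqrt(4 - x^2) / (4 * pi) + asin(x / 2) / pi
}

# standardized matrix from plain random data
random_std <- function(n, d) standardize(matrix(stats::rnorm(n * d), n, d))
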