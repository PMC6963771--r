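# structure_io: PDB reading, shared atom sets, superposition, matrix I/O.

test_that("read_calpha parses a minimal fixture in canonical order", {
  s <- read_calpha(three_residue_pdb())
  expect_s3_class(s, "ca_structure")
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$keys$resno, 1:3)
  expect_equal(s$keys$chain, rep("A", 3))
  expect_equal(unname(s$xyz[2, ]), c(4, 5, 6))
})

test_that("altloc policies behave as documented", {
  f <- altloc_pdb()
  expect_error(read_calpha(f, altloc_policy = "reject"), "alternate locations")
  # highest occupancy keeps altLoc B (occ 0.6)
  s <- read_calpha(f, altloc_policy = "highest_occupancy")
  expect_equal(n_atoms(s), 3L)
  expect_equal(unname(s$xyz[2, ]), c(2, 2, 2))
  # take_first keeps altLoc A
  s2 <- read_calpha(f, altloc_policy = "take_first")
  expect_equal(unname(s2$xyz[2, ]), c(1, 1, 1))
})

test_that("read_calpha honors chain filter, first MODEL, and error cases", {
  lines <- c(
    pdb_atom_line(1, " CA ", " ", "ALA", "A", 1, " ", 0, 0, 0),
    pdb_atom_line(2, " CA ", " ", "ALA", "A", 2, " ", 1, 0, 0),
    pdb_atom_line(3, " CA ", " ", "ALA", "A", 3, " ", 2, 0, 0),
    pdb_atom_line(4, " CA ", " ", "ALA", "B", 1, " ", 5, 5, 5),
    pdb_atom_line(5, " CA ", " ", "ALA", "B", 2, " ", 6, 5, 5),
    pdb_atom_line(6, " CA ", " ", "ALA", "B", 3, " ", 7, 5, 5),
    "ENDMDL",
    pdb_atom_line(7, " CA ", " ", "ALA", "C", 9, " ", 9, 9, 9))
  f <- write_pdb_fixture(lines)
  s <- read_calpha(f)
  expect_equal(sort(unique(s$keys$chain)), c("A", "B"))  # model 2 dropped
  sA <- read_calpha(f, chain_filter = "A")
  expect_equal(unique(sA$keys$chain), "A")
  expect_equal(n_atoms(sA), 3L)
  # no CA at all
  f2 <- write_pdb_fixture(pdb_atom_line(1, " N  ", " ", "ALA", "A", 1, " ", 0, 0, 0))
  expect_error(read_calpha(f2), "no C-alpha")
})

test_that("common_atom_set intersects keys in canonical order", {
  mk <- function(id, resnos) ca_structure(id, rep("A", length(resnos)), resnos,
                                          rep("", length(resnos)),
                                          matrix(seq_len(3 * length(resnos)),
                                                 ncol = 3))
  a <- mk("a", 1:10); b <- mk("b", 3:12)
  expect_equal(common_atom_set(list(a, a)), paste("A", 1:10, "", sep = ":"))
  ks <- common_atom_set(list(a, b))
  expect_equal(length(ks), 8L)
  expect_equal(ks, paste("A", 3:10, "", sep = ":"))
  disjoint <- mk("c", 20:29)
  expect_error(common_atom_set(list(a, disjoint)), "'c'")
})

test_that("superposition exactly recovers a rigid transform and is rigid itself", {
  set.seed(42)
  for (rep in 1:5) {
    a <- random_structure(20, "a")
    b <- apply_rigid(a, random_rigid()); b$entry_id <- "b"
    sup <- superpose_ensemble(list(a, b), reference = "first")
    expect_lt(rmsd(sup[[1]], sup[[2]]), 1e-10)
    # rigid-body contract: intra-structure distances untouched
    expect_lt(max(abs(dist(sup[[2]]$xyz) - dist(b$xyz))), 1e-9)
  }
})

test_that("superposing a structure onto itself (reference first) is the identity", {
  set.seed(7)
  a <- random_structure(15)
  sup <- superpose_ensemble(list(a, a), reference = "first")
  expect_equal(sup[[1]]$xyz, a$xyz, tolerance = 1e-12)
})

test_that("mirror images are fit with a proper rotation, never a reflection", {
  # 4-atom chiral toy; brute-force over many proper rotations as the oracle
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 3.8))
  a <- ca_structure("a", rep("A", 4), 1:4, rep("", 4), xyz)
  m <- a; m$entry_id <- "m"; m$xyz[, 1] <- -m$xyz[, 1]   # mirror
  sup <- superpose_ensemble(list(a, m), reference = "first")
  fitted_rmsd <- rmsd(sup[[1]], sup[[2]])
  expect_gt(fitted_rmsd, 0.1)                            # cannot vanish
  # oracle: best achievable RMSD over random proper rotations (+ centroid match)
  set.seed(11)
  ctr_a <- sweep(xyz, 2, colMeans(xyz)); ctr_m <- sweep(m$xyz, 2, colMeans(m$xyz))
  best <- Inf
  for (i in 1:4000) {
    q <- qr(matrix(rnorm(9), 3)); R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    best <- min(best, sqrt(mean(rowSums((ctr_m %*% R - ctr_a)^2))))
  }
  expect_lte(fitted_rmsd, best + 1e-6)                   # Kabsch is optimal
})

test_that("iterative-mean frame is invariant to a global rigid motion", {
  set.seed(5)
  structures <- lapply(1:6, function(i) random_structure(25, paste0("s", i)))
  sup1 <- superpose_ensemble(structures)
  motion <- random_rigid()
  sup2 <- superpose_ensemble(lapply(structures, apply_rigid, motion = motion))
  for (i in seq_along(sup1))
    expect_equal(sup1[[i]]$xyz, sup2[[i]]$xyz, tolerance = 1e-6)
})

test_that("build_matrix lays out rows and columns as specified", {
  a <- ca_structure("a", c("A", "A", "A"), 1:3, rep("", 3),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)))
  b <- ca_structure("b", c("A", "A", "A"), 1:3, rep("", 3),
                    rbind(c(1, 0, 0), c(2, 0, 0), c(1, 2, 0)))
  m <- build_matrix(list(a, b))
  expect_equal(dim(m), c(2L, 9L))
  expect_equal(rownames(m), c("a", "b"))
  expect_equal(unname(m["a", 1:6]), c(0, 0, 0, 1, 0, 0))
  # single shared atom across structures
  m1 <- build_matrix(list(a, b), atom_keys = "A:2:")
  expect_equal(unname(m1[, 1:3]), rbind(c(1, 0, 0), c(2, 0, 0)))
  # shape contract K x 3M on random ensembles
  set.seed(3)
  for (rep in 1:3) {
    k <- sample(3:7, 1); n <- sample(4:30, 1)
    ens <- lapply(seq_len(k), function(i) random_structure(n, paste0("e", i)))
    expect_equal(dim(build_matrix(ens, common_atom_set(ens))), c(k, 3L * n))
  }
})

test_that("matrix text round trip is lossless to 1e-6 and errors are located", {
  set.seed(9)
  ens <- lapply(1:4, function(i) random_structure(6, paste0("e", i)))
  m <- build_matrix(ens)
  f <- tempfile(fileext = ".tsv")
  write_matrix(m, f)
  m2 <- read_matrix(f)
  expect_equal(rownames(m2), rownames(m))
  expect_equal(colnames(m2), colnames(m))
  expect_lt(max(abs(m2 - m)), 1e-6)
  expect_equal(attr(m2, "atom_keys"), attr(m, "atom_keys"))
  # empty file
  f0 <- tempfile(); writeLines(character(0), f0)
  expect_error(read_matrix(f0), "no data rows")
  # one corrupted cell, error names row and column
  lines <- readLines(f)
  lines[3] <- sub("^(([^\t]*\t){2})[^\t]*", "\\1oops", lines[3])
  writeLines(lines, f)
  expect_error(read_matrix(f), "row 2.*column 2")
})

test_that("write_pdb round trips through read_calpha at format precision", {
  set.seed(14)
  s <- random_structure(10)
  s$xyz[1, ] <- c(-123.456, -0.001, 999.999)   # negative, right-justified fields
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_calpha(f)
  expect_equal(s2$keys, s$keys, ignore_attr = TRUE)
  expect_lt(max(abs(s2$xyz - s$xyz)), 1e-3 + 1e-12)
  expect_equal(unname(s2$xyz[1, 1]), -123.456)
  # idempotence: read -> write -> read
  f3 <- tempfile(fileext = ".pdb")
  write_pdb(s2, f3)
  expect_equal(read_calpha(f3)$xyz, s2$xyz)
})
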