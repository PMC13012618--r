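# Order parameters and PCA against independent analytic oracles.

test_that("dihedral agrees with an independent oracle on random quadruples", {
  set.seed(10)
  top <- topology(name = rep("C", 4), resid = rep(1, 4),
                  resname = rep("UNK", 4), element = rep("C", 4))
  for (rep_i in 1:1000) {
    pts <- matrix(rnorm(12), 4, 3)
    ens <- frame_ensemble(top, pts)
    got <- as.numeric(dihedral_series(ens, 1:4))
    want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_lt(abs(allonet:::wrap_angle(got - want)), 1e-9)
  }
})

test_that("dihedral sign flips under mirror reflection", {
  fx <- make_geometry_fixture("dihedral", angle = 72)
  mirrored <- fx$ensemble
  mirrored$coords[, , 3] <- -mirrored$coords[, , 3]
  expect_equal(as.numeric(dihedral_series(mirrored, 1:4)), -72,
               tolerance = 1e-9)
})

test_that("subdomain torsion reproduces fixtures and a COM+dihedral oracle", {
  fx <- make_geometry_fixture("lobe_torsion", angle = 35)
  groups <- lapply(1:4, function(r)
    select_atoms(fx$topology, paste("resid", r)))
  expect_equal(as.numeric(subdomain_torsion(fx$ensemble, groups)), 35,
               tolerance = 1e-6)

  # noisy ensemble vs independently computed group means
  set.seed(11)
  n <- 12
  top <- topology(name = rep(c("N", "CA", "C"), 4),
                  resid = rep(1:4, each = 3), resname = rep("GLY", n))
  coords <- array(rnorm(5 * n * 3), dim = c(5, n, 3))
  ens <- frame_ensemble(top, coords)
  groups <- lapply(1:4, function(r) select_atoms(top, paste("resid", r)))
  got <- as.numeric(subdomain_torsion(ens, groups))
  masses <- c(14.007, 12.011, 12.011)   # N, CA, C
  for (f in 1:5) {
    coms <- lapply(1:4, function(g)
      colSums(coords[f, (g - 1) * 3 + 1:3, ] * masses) / sum(masses))
    want <- oracle_dihedral(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
    expect_lt(abs(allonet:::wrap_angle(got[f] - want)), 1e-9)
  }
})

test_that("four coplanar trans groups give 180 degrees", {
  fx <- make_geometry_fixture("lobe_torsion", angle = 180)
  groups <- lapply(1:4, function(r)
    select_atoms(fx$topology, paste("resid", r)))
  expect_equal(abs(as.numeric(subdomain_torsion(fx$ensemble, groups))),
               180, tolerance = 1e-6)
})

test_that("group distances match direct computation in both modes", {
  top <- topology(name = c("CA", "CA"), resid = 1:2,
                  resname = c("ALA", "ALA"), element = c("C", "C"))
  ens <- frame_ensemble(top, rbind(c(0, 0, 0), c(0.35, 0, 0)))
  a <- select_atoms(top, "resid 1")
  b <- select_atoms(top, "resid 2")
  expect_equal(as.numeric(group_distance(ens, a, b, "com")), 0.35)
  expect_equal(as.numeric(group_distance(ens, a, b, "min")), 0.35)
  expect_equal(as.numeric(group_distance(ens, a, a, "com")), 0)

  # min mode equals brute-force all-pairs minimum on a random system
  set.seed(12)
  g <- make_planted_network_ensemble(n_frames = 100, seed = 8)
  sa <- select_atoms(g$topology, "resid 1-10")
  sb <- select_atoms(g$topology, "resid 20-30")
  got <- as.numeric(group_distance(g$ensemble, sa, sb, "min"))
  for (f in c(1, 50, 100)) {
    xyz <- get_frame(g$ensemble, f)
    want <- min(as.matrix(dist(xyz))[1:10, 20:30])
    expect_equal(got[f], want, tolerance = 1e-12)
  }
})

test_that("PCA recovers a diagonal covariance and its identities", {
  set.seed(13)
  top <- topology(name = c("CA", "CA"), resid = 1:2,
                  resname = c("ALA", "ALA"))
  n <- 30000
  vars <- c(9, 1, 1, 1, 1, 1) * 1e-4
  x <- sapply(seq_along(vars), function(j) rnorm(n, sd = sqrt(vars[j])))
  coords <- array(NA_real_, dim = c(n, 2, 3))
  coords[, 1, 1] <- x[, 1]; coords[, 2, 1] <- x[, 2]
  coords[, 1, 2] <- x[, 3]; coords[, 2, 2] <- x[, 4]
  coords[, 1, 3] <- x[, 5]; coords[, 2, 3] <- x[, 6]
  ens <- frame_ensemble(top, coords)
  p <- pca_ensemble(ens, select_atoms(top, "all"))
  expect_equal(p$variance_fraction[1], 9 / 14, tolerance = 0.02)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  # projections: zero mean, variance equal to eigenvalues
  expect_lt(abs(mean(p$projections[, 1])), 1e-9)
  expect_equal(var(p$projections[, 1]) * (n - 1) / n,
               p$eigenvalues[1] * (n - 1) / n, tolerance = 1e-9)
})

test_that("PCA is invariant to frame duplication and atom order", {
  set.seed(14)
  g <- make_planted_network_ensemble(n_frames = 300, seed = 9)
  fit <- select_atoms(g$topology, "all")
  p1 <- suppressWarnings(pca_ensemble(g$ensemble, fit))
  dup <- merge_ensembles(g$ensemble, g$ensemble)
  p2 <- suppressWarnings(pca_ensemble(dup, fit))
  expect_equal(p1$variance_fraction, p2$variance_fraction,
               tolerance = 1e-9)
  # atom permutation leaves the spectrum unchanged
  perm <- sample(n_atoms(g$topology))
  permuted <- frame_ensemble(
    topology(name = g$topology$atoms$name[perm],
             resid = seq_along(perm),
             resname = g$topology$atoms$resname[perm]),
    g$ensemble$coords[, perm, , drop = FALSE])
  p3 <- suppressWarnings(
    pca_ensemble(permuted, select_atoms(permuted$topology, "all")))
  expect_equal(p1$variance_fraction, p3$variance_fraction,
               tolerance = 1e-9)
})

test_that("pca_project reproduces the fit-set scores", {
  g <- make_planted_network_ensemble(n_frames = 200, seed = 10)
  fit <- select_atoms(g$topology, "all")
  p <- suppressWarnings(pca_ensemble(g$ensemble, fit))
  proj <- pca_project(p, g$ensemble, components = 1)
  expect_equal(as.numeric(proj), as.numeric(p$projections[, 1]),
               tolerance = 1e-12)
})

test_that("squared correlation handles affine, null and oracle cases", {
  set.seed(15)
  a <- rnorm(1000)
  expect_equal(correlate_series(a, 2 * a + 1), 1, tolerance = 1e-12)
  b <- rnorm(10000); c_ <- rnorm(10000)
  expect_lt(correlate_series(b, c_), 0.01)
  # covariance-ratio oracle
  x <- rnorm(500); y <- 0.4 * x + rnorm(500)
  want <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_series(x, y), want, tolerance = 1e-12)
  expect_error(correlate_series(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("histograms are normalized probability densities", {
  h <- series_histogram(rep(2.5, 100), breaks = 0:5)
  expect_equal(h$density[3], 1)
  expect_equal(sum(h$density * diff(0:5)), 1, tolerance = 1e-12)
  set.seed(16)
  u <- runif(1e5)
  h2 <- series_histogram(u, breaks = seq(0, 1, 0.1))
  expect_true(all(abs(h2$density - 1) < 0.05))
  expect_error(series_histogram(numeric(0), 0:1), "empty")
})
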