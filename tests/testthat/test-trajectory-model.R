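# Topology/ensemble types, selection grammar, file round trips and
# superposition.

make_toy <- function(n_res = 5, n_frames = 3, sd = 0.3, seed = 1) {
  set.seed(seed)
  top <- topology(name = rep(c("N", "CA", "C", "O"), n_res),
                  resid = rep(seq_len(n_res), each = 4),
                  resname = rep("ALA", 4 * n_res))
  coords <- array(rnorm(n_frames * 4 * n_res * 3, sd = sd),
                  dim = c(n_frames, 4 * n_res, 3))
  frame_ensemble(top, coords)
}

test_that("topology enforces atom/residue bookkeeping", {
  top <- topology(name = c("N", "CA", "C"), resid = c(1, 1, 1),
                  resname = rep("ALA", 3))
  expect_equal(n_atoms(top), 3)
  expect_equal(nrow(top$residues), 1)
  expect_error(topology(name = character(0), resid = integer(0),
                        resname = character(0)), "at least one atom")
  expect_error(
    topology(name = c("CA", "CA"), resid = c(2, 1),
             resname = c("ALA", "ALA")), "non-decreasing")
  # element inference from atom names
  expect_equal(top$atoms$element, c("N", "C", "C"))
})

test_that("frame ensembles validate shape against their topology", {
  top <- topology(name = c("CA", "CA"), resid = 1:2,
                  resname = c("ALA", "GLY"))
  expect_error(frame_ensemble(top, array(0, dim = c(1, 3, 3))),
               "does not match")
  ens <- frame_ensemble(top, matrix(0, 2, 3))
  expect_equal(n_frames(ens), 1)
})

test_that("selection grammar matches independent enumeration", {
  ens <- make_toy(n_res = 200)
  top <- ens$topology
  sel <- select_atoms(top, "resid 40-115 and backbone")
  expected <- which(top$atoms$resid >= 40 & top$atoms$resid <= 115 &
                      top$atoms$name %in% c("N", "CA", "C", "O"))
  expect_identical(sel$indices, as.integer(expected))
  # multi-range, union, negation
  sel2 <- select_atoms(top, "resid 1-39 116-188 and calpha")
  expect_equal(length(sel2), 39 + 73)
  sel3 <- select_atoms(top, "not (resid 1-100)")
  expect_equal(length(sel3), 100 * 4)
  # purity: repeated calls identical
  expect_identical(select_atoms(top, "calpha")$indices,
                   select_atoms(top, "calpha")$indices)
})

test_that("selection errors are raised, not silently empty", {
  ens <- make_toy()
  top <- ens$topology
  expect_error(select_atoms(top, "resid 5-4"), "empty residue range")
  expect_error(select_atoms(top, "name XX"), "unknown name")
  expect_error(select_atoms(top, "resname LYS"), "unknown resname")
  expect_error(select_atoms(top, "resid 999"), "unknown residue id")
  expect_error(select_atoms(top, "and backbone"), "syntax")
  expect_error(select_atoms(top, "(backbone"), "missing ')'")
})

test_that("PDB and GRO round trips preserve coordinates to format precision", {
  ens <- make_toy(n_frames = 5)
  for (fmt in c("pdb", "gro")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(ens, path)
    back <- read_structure(path)
    expect_equal(n_frames(back$ensemble), 5)
    expect_equal(back$topology$atoms$resid, ens$topology$atoms$resid)
    expect_equal(back$topology$atoms$name, ens$topology$atoms$name)
    expect_lt(max(abs(back$ensemble$coords - ens$coords)), 1e-3)
  }
})

test_that("GRO and PDB writers agree on the same coordinates", {
  ens <- make_toy(n_frames = 1)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".gro")
  write_structure(ens, p1)
  write_structure(ens, p2)
  a <- read_structure(p1)$ensemble$coords
  b <- read_structure(p2)$ensemble$coords
  expect_lt(max(abs(a - b)), 1e-3)
})

test_that("trajectory round trips (DCD and multi-model PDB) preserve frames", {
  ens <- make_toy(n_frames = 100)
  for (fmt in c("dcd", "pdb")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trajectory(ens, path)
    back <- read_trajectory(ens$topology, path)
    expect_equal(n_frames(back), 100)
    expect_lt(max(abs(back$coords - ens$coords)), 1e-3)
  }
})

test_that("trajectory atom-count mismatch is an error", {
  ens <- make_toy(n_res = 5)
  other <- make_toy(n_res = 6)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(ens, path)
  expect_error(read_trajectory(other$topology, path),
               "does not match")
})

test_that("superpose undoes rigid motions exactly and is idempotent", {
  ens <- make_toy(n_frames = 1, seed = 3)
  xyz <- get_frame(ens, 1)
  th <- c(0.4, -1.2)
  frames <- list(xyz)
  for (t in th) {
    rot <- matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    frames[[length(frames) + 1]] <- xyz %*% rot +
      matrix(rep(c(1, -2, 0.5), each = nrow(xyz)), ncol = 3)
  }
  rigid <- bead_ensemble(frames)
  fit <- atom_selection(seq_len(nrow(xyz)), rigid$topology, "all")
  out <- superpose(rigid, fit)
  expect_lt(max(attr(out, "rmsd")), 1e-6)
  # idempotence
  out2 <- superpose(out, fit)
  expect_lt(max(abs(attr(out2, "rmsd") - attr(out, "rmsd"))), 1e-9)
  # identity ensemble: transforms are identity within tolerance
  ident <- bead_ensemble(list(xyz, xyz))
  outi <- superpose(ident, fit)
  expect_lt(max(abs(outi$coords[2, , ] - xyz)), 1e-12)
})

test_that("superpose matches an independent least-squares fit on noisy data", {
  set.seed(7)
  ens <- make_toy(n_frames = 10, seed = 5)
  noisy <- ens$coords
  for (f in 2:10) noisy[f, , ] <- noisy[1, , ] +
    rnorm(length(noisy[1, , ]), sd = 0.02)
  nens <- frame_ensemble(ens$topology, noisy)
  fit <- atom_selection(seq_len(n_atoms(ens$topology)), ens$topology)
  out <- superpose(nens, fit)
  ref <- get_frame(nens, 1)
  for (f in 2:10) {
    expect_lt(abs(attr(out, "rmsd")[f] -
                    oracle_fit_rmsd(get_frame(nens, f), ref)), 1e-9)
  }
})

test_that("degenerate fit selections are rejected", {
  top <- topology(name = rep("CA", 3), resid = 1:3,
                  resname = rep("ALA", 3))
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  ens <- frame_ensemble(top, collinear)
  expect_error(superpose(ens, atom_selection(1:3, top)),
               "collinear")
  expect_error(superpose(ens, atom_selection(1:2, top)), "at least 3")
})
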