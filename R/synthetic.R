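# Synthetic-data generators with machine-readable ground truth.
#
# Every generator is deterministic under its seed and emits a ground_truth
# object sufficient to score the downstream stage. The ensembles are
# statistical/geometric stand-ins (Gaussian fluctuations around a bead
# lattice), not a model of real protein dynamics.

#' Ground-truth container emitted by the synthetic generators
#' @param planted_path ordered residue ids of the planted allosteric chain
#' @param planted_partition named integer vector residue -> community label
#' @param analytic_pmf data.frame with `xi` (nm) and `G_kT` (min-anchored)
#' @param scripted_contacts data.frame (i, j, type, expected_freq)
#' @return object of class `ground_truth`
#' @export
ground_truth <- function(planted_path = NULL, planted_partition = NULL,
                         analytic_pmf = NULL, scripted_contacts = NULL) {
  if (is.null(planted_path) && is.null(planted_partition) &&
      is.null(analytic_pmf) && is.null(scripted_contacts))
    stop("ground truth must populate at least one field")
  if (!is.null(analytic_pmf) && any(diff(analytic_pmf$xi) <= 0))
    stop("analytic_pmf grid must be strictly increasing")
  structure(list(planted_path = planted_path,
                 planted_partition = planted_partition,
                 analytic_pmf = analytic_pmf,
                 scripted_contacts = scripted_contacts),
            class = "ground_truth")
}

# Bead-lattice helpers ------------------------------------------------------

# Serpentine grid positions: residue i (1-based) on an n_rows x n_cols grid,
# filled row by row, alternating direction, spacing in nm. Row-adjacent and
# column-adjacent beads are exactly `spacing` apart, diagonals sqrt(2) x.
.serpentine_positions <- function(n, n_rows, n_cols, spacing = 0.38) {
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% n_cols
    within <- (i - 1) %% n_cols
    c <- if (r %% 2 == 0) within else n_cols - 1 - within
    pos[i, ] <- c(c * spacing, r * spacing, 0)
  }
  pos
}

.bead_topology <- function(n, resname = "ALA") {
  topology(name = rep("CA", n), resid = seq_len(n),
           resname = rep(resname, n), element = rep("C", n))
}

# Draw F frames of per-residue 3-D Gaussian displacements whose per-dimension
# residue-residue covariance is sigma^2 * C (the three dimensions are
# independent and identically coupled).
.sample_gaussian_frames <- function(base, C, sigma, n_frames) {
  n <- nrow(base)
  ch <- tryCatch(chol(C), error = function(e)
    stop("correlation structure is not positive-definite; ",
         "reduce the planted correlation: ", conditionMessage(e)))
  coords <- array(NA_real_, dim = c(n_frames, n, 3))
  for (d in 1:3) {
    z <- matrix(stats::rnorm(n_frames * n), n_frames, n) %*% ch
    coords[, , d] <- sweep(sigma * z, 2, base[, d], `+`)
  }
  coords
}

#' Bead-chain ensemble with a planted correlated path
#'
#' Builds a serpentine bead lattice (one C-alpha-like atom per residue,
#' neighbouring beads 0.38 nm apart so lattice edges pass the contact
#' persistence rule) and draws frames from a zero-mean multivariate Gaussian
#' in which the residues of one lattice column form a first-order Markov
#' chain with per-link, per-dimension correlation `rho`. Off-chain lattice
#' neighbours receive a weak background coupling `rho_bg` so the rest of the
#' graph still carries edges. The planted column is the known allosteric
#' path the network stage is expected to recover.
#'
#' @param n_residues number of beads (must fill the lattice; default 30)
#' @param n_intermediates beads between source and sink on the planted
#'   chain (chain length is `n_intermediates + 2`)
#' @param rho per-link correlation of the planted chain, in `[0, 1)`
#' @param rho_bg background nearest-neighbour correlation for off-chain
#'   lattice pairs
#' @param sigma fluctuation amplitude per dimension (nm)
#' @param n_frames number of frames (>= 100)
#' @param seed random seed (mandatory)
#' @return list with `topology`, `ensemble`, `truth` (a [ground_truth()]
#'   with `planted_path`)
#' @export
make_planted_network_ensemble <- function(n_residues = 30,
                                          n_intermediates = 4,
                                          rho = 0.8, rho_bg = 0.05,
                                          sigma = 0.03, n_frames = 5000,
                                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (n_frames < 100) stop("n_frames must be >= 100")
  n_rows <- n_intermediates + 2
  n_cols <- n_residues %/% n_rows
  if (n_rows * n_cols != n_residues)
    stop("n_residues must be a multiple of n_intermediates + 2 ",
         "(lattice rows)")
  set.seed(seed)
  base <- .serpentine_positions(n_residues, n_rows, n_cols)
  # planted chain: the middle lattice column, bottom row to top row
  c_mid <- (n_cols - 1) %/% 2
  chain <- vapply(seq_len(n_rows) - 1, function(r) {
    within <- if (r %% 2 == 0) c_mid else n_cols - 1 - c_mid
    as.integer(r * n_cols + within + 1)
  }, integer(1))

  C <- diag(n_residues)
  # Markov-chain block on the planted column: cov = rho^|i-j|
  L <- length(chain)
  C[chain, chain] <- rho^abs(outer(seq_len(L), seq_len(L), `-`))
  # weak coupling on off-chain lattice-neighbour pairs
  nb <- .lattice_neighbours(n_residues, n_rows, n_cols)
  for (k in seq_len(nrow(nb))) {
    i <- nb[k, 1]; j <- nb[k, 2]
    if (!(i %in% chain) && !(j %in% chain)) {
      C[i, j] <- C[j, i] <- rho_bg
    }
  }
  top <- .bead_topology(n_residues)
  coords <- .sample_gaussian_frames(base, C, sigma, n_frames)
  list(topology = top,
       ensemble = frame_ensemble(top, coords),
       truth = ground_truth(planted_path = chain))
}

# All lattice-neighbour pairs (sequence neighbours and same-column
# row-adjacent beads) of the serpentine grid.
.lattice_neighbours <- function(n, n_rows, n_cols, spacing = 0.38) {
  pos <- .serpentine_positions(n, n_rows, n_cols, spacing)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < spacing * 1.05) out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Two-block ensemble with a planted community structure
#'
#' Two compact bead blocks (two-row serpentine grids laid side by side) with
#' equicorrelated motion inside each block and independent motion between
#' blocks. Louvain community detection on the resulting dynamic network is
#' expected to recover the block labels.
#'
#' @param block_sizes integer vector of block sizes (default `c(10, 10)`)
#' @param rho_within within-block per-dimension correlation
#' @param sigma fluctuation amplitude (nm)
#' @param n_frames number of frames
#' @param seed random seed (mandatory)
#' @return list with `topology`, `ensemble`, `truth` (with
#'   `planted_partition`)
#' @export
make_planted_partition_ensemble <- function(block_sizes = c(10, 10),
                                            rho_within = 0.6,
                                            sigma = 0.03, n_frames = 3000,
                                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- sum(block_sizes)
  base <- matrix(NA_real_, n, 3)
  labels <- integer(n)
  C <- diag(n)
  at <- 0L
  x_off <- 0
  for (b in seq_along(block_sizes)) {
    m <- block_sizes[b]
    # compact cluster: centre bead plus a Fibonacci sphere of radius
    # 0.15 nm, so every within-block pair sits well inside the contact
    # cutoff (dense internal edges); cluster centres 0.62 nm apart leave
    # only a few weak bridge edges between facing beads
    pos <- rbind(c(0, 0, 0), .fibonacci_sphere(m - 1, 0.15))
    pos[, 1] <- pos[, 1] + x_off
    idx <- at + seq_len(m)
    base[idx, ] <- pos
    labels[idx] <- b
    C[idx, idx] <- rho_within + diag(1 - rho_within, m)
    at <- at + m
    x_off <- x_off + 0.62
  }
  top <- .bead_topology(n)
  coords <- .sample_gaussian_frames(base, C, sigma, n_frames)
  names(labels) <- seq_len(n)
  list(topology = top,
       ensemble = frame_ensemble(top, coords),
       truth = ground_truth(planted_partition = labels))
}

# Deterministic quasi-uniform points on a sphere of given radius.
.fibonacci_sphere <- function(m, radius) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Umbrella sampling ---------------------------------------------------------

#' Evaluate a named 1-D potential (kJ/mol)
#' @param potential list: `list(kind = "harmonic", kappa, xi0)` or
#'   `list(kind = "double_well", barrier, minima = c(m1, m2))` or
#'   `list(kind = "flat")`
#' @param xi coordinate values (nm)
#' @return potential energy in kJ/mol
#' @export
eval_potential <- function(potential, xi) {
  switch(potential$kind,
    flat = rep(0, length(xi)),
    harmonic = 0.5 * potential$kappa * (xi - potential$xi0)^2,
    double_well = {
      m <- mean(potential$minima)
      a <- diff(potential$minima) / 2
      q <- (xi - m)^2 - a^2
      potential$barrier * q^2 / a^4
    },
    stop("unknown potential kind '", potential$kind, "'")
  )
}

#' Generate an umbrella-sampling dataset from a known potential
#'
#' Draws per-window samples from the biased Boltzmann density
#' p_i(xi) ~ exp(-(U(xi) + k/2 (xi - xi_i)^2) / kBT). Harmonic (and flat)
#' potentials are sampled exactly from the closed-form Gaussian; other
#' potentials use a Metropolis chain (1000-step burn-in, keep every 20th
#' step) whose acceptance rate and residual lag-1 autocorrelation are
#' checked. The analytic min-anchored free-energy profile is returned as
#' ground truth.
#'
#' @param potential potential spec, see [eval_potential()]
#' @param windows window centers (nm, sorted; default ten equally spaced
#'   windows spanning 0.3 to 1.2 nm)
#' @param k spring constant of the harmonic bias (kJ mol^-1 nm^-2,
#'   default 1500)
#' @param n samples per window (>= 100)
#' @param temperature K (default 310)
#' @param seed random seed (mandatory)
#' @param dt_ps nominal sampling interval for the emitted time column (ps)
#' @return list with `dataset` (an `umbrella_dataset`) and `truth`
#'   (with `analytic_pmf`)
#' @export
make_umbrella_dataset <- function(potential = list(kind = "harmonic",
                                                   kappa = 100, xi0 = 0.6),
                                  windows = seq(0.3, 1.2, length.out = 10),
                                  k = 1500, n = 5000,
                                  temperature = 310, seed, dt_ps = 100) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.unsorted(windows)) stop("windows must be sorted")
  if (k <= 0) stop("spring constant must be positive")
  if (n < 100) stop("need at least 100 samples per window")
  set.seed(seed)
  kT <- kBT_kJ(temperature)
  win <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    ctr <- windows[w]
    if (potential$kind %in% c("harmonic", "flat")) {
      kappa <- if (potential$kind == "harmonic") potential$kappa else 0
      xi0 <- if (potential$kind == "harmonic") potential$xi0 else 0
      prec <- kappa + k
      mu <- (kappa * xi0 + k * ctr) / prec
      xi <- stats::rnorm(n, mean = mu, sd = sqrt(kT / prec))
    } else if (potential$kind == "double_well") {
      m <- mean(potential$minima)
      a <- diff(potential$minima) / 2
      step <- 3 * sqrt(kT / k)
      xi <- metropolis_biased(n, 1000L, 20L, step, 1 / kT,
                              potential$barrier, m, a, k, ctr, ctr)
      if (attr(xi, "acceptance") < 0.05)
        stop("Metropolis acceptance below 5% in window ", w,
             "; check the potential scale")
      ac1 <- stats::cor(xi[-1], xi[-length(xi)])
      if (is.finite(ac1) && abs(ac1) > 0.1)
        stop("thinned Metropolis chain still correlated (lag-1 = ",
             round(ac1, 3), ") in window ", w)
      xi <- as.numeric(xi)
    } else stop("unknown potential kind '", potential$kind, "'")
    win[[w]] <- list(center = ctr, k = k,
                     time = seq_len(n) * dt_ps, xi = xi)
  }
  dataset <- structure(list(windows = win, temperature = temperature),
                       class = "umbrella_dataset")
  lo <- min(windows) - 0.1
  hi <- max(windows) + 0.1
  grid <- seq(lo, hi, length.out = 501)
  U <- eval_potential(potential, grid)
  truth <- ground_truth(analytic_pmf = data.frame(
    xi = grid, G_kT = (U - min(U)) / kT))
  list(dataset = dataset, truth = truth)
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  cat("umbrella_dataset:", length(x$windows), "windows, centers",
      sprintf("%.2f-%.2f nm,", x$windows[[1]]$center,
              x$windows[[length(x$windows)]]$center),
      "T =", x$temperature, "K\n")
  invisible(x)
}

#' Write an umbrella dataset as per-window text files plus metadata
#'
#' Each window becomes a two-column whitespace-delimited file (time ps,
#' xi nm); `windows.tsv` carries center and spring constant per window.
#' @param ds an `umbrella_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_umbrella_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(file = sprintf("window_%02d.xvg",
                                    seq_along(ds$windows)),
                     center = vapply(ds$windows, `[[`, numeric(1), "center"),
                     k = vapply(ds$windows, `[[`, numeric(1), "k"))
  utils::write.table(meta, file.path(dir, "windows.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(as.character(ds$temperature), file.path(dir, "temperature.txt"))
  for (w in seq_along(ds$windows)) {
    utils::write.table(
      data.frame(time = ds$windows[[w]]$time, xi = ds$windows[[w]]$xi),
      file.path(dir, meta$file[w]), sep = " ",
      row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read an umbrella dataset written by [write_umbrella_dataset()]
#' @param dir directory containing `windows.tsv` and per-window files
#' @return an `umbrella_dataset`
#' @export
read_umbrella_dataset <- function(dir) {
  meta <- utils::read.table(file.path(dir, "windows.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  tfile <- file.path(dir, "temperature.txt")
  temperature <- if (file.exists(tfile))
    as.numeric(readLines(tfile)[1]) else .const$T_default
  win <- lapply(seq_len(nrow(meta)), function(w) {
    d <- utils::read.table(file.path(dir, meta$file[w]), header = FALSE)
    if (nrow(d) == 0) stop("empty window file ", meta$file[w])
    list(center = meta$center[w], k = meta$k[w], time = d[[1]], xi = d[[2]])
  })
  structure(list(windows = win, temperature = temperature),
            class = "umbrella_dataset")
}

# Scripted contact fixtures -------------------------------------------------

.contact_tags <- c("hbond_pass", "hbond_fail_angle", "ionic", "pi_stack",
                   "pi_cation", "hydrophobic")

#' Ensemble of scripted residue-pair geometries with known contact outcomes
#'
#' Each script entry places a minimal residue pair realizing (or violating)
#' one typed contact criterion in a chosen subset of frames; in the other
#' frames the pair is moved apart. Entries are separated by 5 nm so they
#' cannot interact.
#'
#' @param script list of entries `list(tag =, present =, distance =)`;
#'   `tag` one of hbond_pass, hbond_fail_angle, ionic, pi_stack, pi_cation,
#'   hydrophobic; `present` a logical vector over frames (recycled);
#'   `distance` optional override of the contact heavy-atom distance (nm)
#' @param n_frames number of frames (default: longest `present` vector)
#' @return list with `topology`, `ensemble`, `truth` (with
#'   `scripted_contacts`)
#' @export
make_contact_script_ensemble <- function(script, n_frames = NULL) {
  for (e in script) {
    if (!e$tag %in% .contact_tags)
      stop("unknown geometry tag '", e$tag, "'")
  }
  n_frames <- n_frames %||% max(vapply(script, function(e)
    length(e$present), integer(1)))
  atoms <- NULL
  placements <- list()   # per entry: present/absent coordinate blocks
  resid_at <- 0L
  for (k in seq_along(script)) {
    e <- script[[k]]
    offset <- c(5 * (k - 1), 0, 0)
    geom <- .contact_geometry(e$tag, e$distance)
    blk <- data.frame(name = geom$name, resid = resid_at + geom$res,
                      resname = geom$resname, stringsAsFactors = FALSE)
    atoms <- rbind(atoms, blk)
    resid_at <- resid_at + 2L
    near <- sweep(geom$xyz, 2, offset, `+`)
    far <- near
    second <- geom$res == 2
    far[second, 1] <- far[second, 1] + 2.5   # move partner residue away
    placements[[k]] <- list(near = near, far = far,
                            present = rep_len(e$present, n_frames),
                            rows = nrow(blk))
  }
  top <- topology(name = atoms$name, resid = atoms$resid,
                  resname = atoms$resname)
  coords <- array(NA_real_, dim = c(n_frames, nrow(atoms), 3))
  at <- 0L
  truth_rows <- NULL
  for (k in seq_along(placements)) {
    p <- placements[[k]]
    rows <- at + seq_len(p$rows)
    for (f in seq_len(n_frames)) {
      coords[f, rows, ] <- if (p$present[f]) p$near else p$far
    }
    e <- script[[k]]
    expected <- if (e$tag == "hbond_fail_angle") 0 else mean(p$present)
    type <- switch(e$tag, hbond_pass = "hbond", hbond_fail_angle = "hbond",
                   ionic = "ionic", pi_stack = "pi_stack",
                   pi_cation = "pi_cation", hydrophobic = "hydrophobic")
    truth_rows <- rbind(truth_rows, data.frame(
      i = min(atoms$resid[rows]), j = max(atoms$resid[rows]),
      type = type, expected_freq = expected, tag = e$tag,
      stringsAsFactors = FALSE))
    at <- at + p$rows
  }
  list(topology = top, ensemble = frame_ensemble(top, coords),
       truth = ground_truth(scripted_contacts = truth_rows))
}

# Minimal residue-pair geometry for one contact tag. Returns atom names,
# residue membership (1 = first residue, 2 = second), residue names and
# coordinates (nm) with the contact formed.
.contact_geometry <- function(tag, distance = NULL) {
  ring <- function(center, radius = 0.14, normal_z = TRUE) {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(center[1] + radius * cos(ang),
          center[2] + radius * sin(ang),
          center[3] + rep(0, 6))
  }
  switch(tag,
    hbond_pass = .hbond_geometry(angle = 165, distance %||% 0.29),
    hbond_fail_angle = .hbond_geometry(angle = 140, distance %||% 0.29),
    ionic = {
      d <- distance %||% 0.35
      list(name = c("CA", "NZ", "CA", "OD1"),
           res = c(1, 1, 2, 2),
           resname = c("LYS", "LYS", "ASP", "ASP"),
           xyz = rbind(c(-0.15, 0, 0), c(0, 0, 0),
                       c(d + 0.15, 0, 0), c(d, 0, 0)))
    },
    hydrophobic = {
      d <- distance %||% 0.35
      list(name = c("CA", "CD1", "CA", "CG1"),
           res = c(1, 1, 2, 2),
           resname = c("LEU", "LEU", "VAL", "VAL"),
           xyz = rbind(c(-0.15, 0, 0), c(0, 0, 0),
                       c(d + 0.15, 0, 0), c(d, 0, 0)))
    },
    pi_stack = {
      d <- distance %||% 0.45
      r1 <- ring(c(0, 0, 0))
      r2 <- ring(c(0, 0, d))   # parallel rings stacked along z
      list(name = rep(c("CA", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"), 2),
           res = rep(c(1, 2), each = 7),
           resname = rep("PHE", 14),
           xyz = rbind(c(0.3, 0, 0), r1, c(0.3, 0, d), r2))
    },
    pi_cation = {
      d <- distance %||% 0.4
      r1 <- ring(c(0, 0, 0))
      list(name = c("CA", "CG", "CD1", "CD2", "CE1", "CE2", "CZ",
                    "CA", "NZ"),
           res = c(rep(1, 7), 2, 2),
           resname = c(rep("PHE", 7), "LYS", "LYS"),
           xyz = rbind(c(0.3, 0, 0), r1, c(0.3, 0, d), c(0, 0, d)))
    },
    stop("unknown geometry tag '", tag, "'")
  )
}

# Serine hydroxyl donating to a glutamate carboxylate oxygen at the given
# D-H...A angle (degrees) and donor-acceptor distance (nm).
.hbond_geometry <- function(angle, d_da) {
  d_dh <- 0.096
  h <- c(0, 0, 0)
  d <- c(d_dh, 0, 0)          # donor heavy atom (OG)
  th <- angle * pi / 180
  u <- c(cos(th), sin(th), 0)  # direction H -> A at `angle` from H -> D (+x)
  # solve |h + r u - d| = d_da for r > 0
  b <- sum(u * (h - d))
  cc <- sum((h - d)^2) - d_da^2
  r <- -b + sqrt(b^2 - cc)
  a <- h + r * u
  list(name = c("CA", "OG", "HG1", "CA", "OE1"),
       res = c(1, 1, 1, 2, 2),
       resname = c("SER", "SER", "SER", "GLU", "GLU"),
       xyz = rbind(d + c(0.15, 0, 0), d, h, a + c(0.15, 0, 0), a))
}

# Geometry fixtures ----------------------------------------------------------

#' Exact geometric fixtures for the order-parameter operations
#'
#' @param kind one of `"dihedral"`, `"lobe_torsion"`, `"ideal_hairpin"`,
#'   `"coil"`
#' @param angle target angle in degrees, in (-180, 180] (dihedral and
#'   lobe_torsion kinds)
#' @param n_frames number of identical frames to emit
#' @return list with `topology` and `ensemble`
#' @export
make_geometry_fixture <- function(kind = c("dihedral", "lobe_torsion",
                                           "ideal_hairpin", "coil"),
                                  angle = NULL, n_frames = 1) {
  kind <- match.arg(kind)
  if (kind %in% c("dihedral", "lobe_torsion")) {
    if (is.null(angle) || angle <= -180 || angle > 180)
      stop("angle must be in (-180, 180]")
  }
  out <- switch(kind,
    dihedral = {
      pts <- .dihedral_points(angle)
      top <- topology(name = c("C1", "C2", "C3", "C4"), resid = rep(1, 4),
                      resname = rep("UNK", 4), element = rep("C", 4))
      list(topology = top, xyz = pts)
    },
    lobe_torsion = {
      pts <- .dihedral_points(angle)
      # each dihedral point becomes the mean of a 3-atom group (offsets
      # cancel; equal masses keep the centre of mass on the point)
      off <- rbind(c(0.05, 0, 0), c(-0.05, 0.02, 0), c(0, -0.02, 0))
      xyz <- NULL
      for (g in 1:4) xyz <- rbind(xyz, sweep(off, 2, pts[g, ], `+`))
      top <- topology(name = rep(c("N", "CA", "C"), 4),
                      resid = rep(1:4, each = 3),
                      resname = rep("GLY", 12))
      list(topology = top, xyz = xyz)
    },
    ideal_hairpin = {
      tpl <- antiparallel_template()
      top <- topology(name = tpl$name, resid = tpl$resid,
                      resname = rep("ALA", length(tpl$name)))
      list(topology = top, xyz = tpl$xyz)
    },
    coil = {
      # tight helix: far from the extended antiparallel template
      tpl <- antiparallel_template()
      nres <- 6
      t <- seq(0, 4 * pi, length.out = nres * 5)
      xyz <- cbind(0.12 * cos(t), 0.12 * sin(t), 0.05 * t / pi)
      top <- topology(name = rep(c("N", "CA", "CB", "C", "O"), nres),
                      resid = rep(seq_len(nres), each = 5),
                      resname = rep("ALA", nres * 5))
      list(topology = top, xyz = xyz)
    })
  coords <- array(rep(t(out$xyz), n_frames),
                  dim = c(3, nrow(out$xyz), n_frames))
  coords <- aperm(coords, c(3, 2, 1))
  list(topology = out$topology,
       ensemble = frame_ensemble(out$topology, coords))
}

# Four points realizing a requested signed dihedral exactly: the central
# bond lies on x, the first point fixes the reference half-plane, the
# fourth is rotated about the bond. The construction is verified against
# the analytic dihedral and mirrored if the sign convention differs.
.dihedral_points <- function(angle) {
  phi <- angle * pi / 180
  p2 <- c(0, 0, 0)
  p3 <- c(0.15, 0, 0)
  p1 <- c(-0.05, 0.15, 0)
  p4 <- p3 + c(0.05, 0.15 * cos(phi), 0.15 * sin(phi))
  pts <- rbind(p1, p2, p3, p4)
  got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  if (abs(wrap_angle(got - angle)) > 1e-9) {
    pts[, 3] <- -pts[, 3]
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    if (abs(wrap_angle(got - angle)) > 1e-9)
      stop("internal error: dihedral construction failed")
  }
  pts
}
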