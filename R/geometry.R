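# Order parameters: subdomain torsion, dihedrals, group distances,
# series containers, and PCA on ensemble coordinates.

#' Order-parameter series
#' @param name series label
#' @param values per-frame values
#' @param units "deg", "nm" or "dimensionless"
#' @return object of class `op_series`
#' @export
op_series <- function(name, values, units) {
  structure(list(name = name, values = as.numeric(values), units = units),
            class = "op_series")
}

#' @export
print.op_series <- function(x, ...) {
  cat(sprintf("op_series '%s': %d frames (%s), mean %.4g\n",
              x$name, length(x$values), x$units, mean(x$values)))
  invisible(x)
}

#' @export
as.double.op_series <- function(x, ...) x$values

#' @export
length.op_series <- function(x) length(x$values)

#' Export an order-parameter series as TSV (frame, value)
#' @param x an `op_series`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_series <- function(x, path) {
  utils::write.table(
    data.frame(frame = seq_along(x$values), value = x$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Mass-weighted centre of mass of a selection in each frame: F x 3 matrix.
.com_series <- function(ens, sel) {
  idx <- sel$indices
  if (length(idx) == 0) stop("empty selection")
  m <- ens$topology$atoms$mass[idx]
  w <- m / sum(m)
  f <- n_frames(ens)
  out <- matrix(NA_real_, f, 3)
  for (d in 1:3) out[, d] <- ens$coords[, idx, d, drop = FALSE][, , 1] %*% w
  out
}

#' Pseudo-torsion angle between four atom-group centres of mass
#'
#' The per-frame signed dihedral of the mass-weighted centres of mass of
#' four atom groups (degrees). This is the inter-subdomain torsion used to
#' track rotation of nucleotide-binding-domain lobes.
#'
#' @param ens a `frame_ensemble`
#' @param groups list of four non-empty `atom_selection`s
#' @return an `op_series` in degrees
#' @export
subdomain_torsion <- function(ens, groups) {
  if (length(groups) != 4) stop("need exactly four groups")
  coms <- lapply(groups, function(g) .com_series(ens, g))
  for (g in 1:3) {
    if (any(rowSums((coms[[g]] - coms[[g + 1]])^2) < 1e-20))
      stop("consecutive group centres of mass coincide")
  }
  vals <- dihedral_angle(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
  op_series("subdomain_torsion", vals, "deg")
}

#' Signed dihedral series over four atoms
#' @param ens a `frame_ensemble`
#' @param atoms four distinct atom indices
#' @return an `op_series` in degrees
#' @export
dihedral_series <- function(ens, atoms) {
  atoms <- as.integer(atoms)
  if (length(atoms) != 4 || anyDuplicated(atoms))
    stop("need four distinct atom indices")
  p <- lapply(1:4, function(k) matrix(ens$coords[, atoms[k], ],
                                      ncol = 3))
  b2 <- p[[3]] - p[[2]]; b1 <- p[[2]] - p[[1]]
  crossn <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
                  b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
                  b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  if (any(rowSums(crossn^2) < 1e-20))
    stop("collinear atoms: dihedral undefined")
  vals <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  op_series("dihedral", vals, "deg")
}

#' Distance between two atom groups per frame
#'
#' @param ens a `frame_ensemble`
#' @param a,b non-empty `atom_selection`s
#' @param mode `"com"` (centre-of-mass distance) or `"min"` (minimum over
#'   all cross pairs)
#' @return an `op_series` in nm
#' @export
group_distance <- function(ens, a, b, mode = c("com", "min")) {
  mode <- match.arg(mode)
  if (length(a$indices) == 0 || length(b$indices) == 0)
    stop("empty selection")
  f <- n_frames(ens)
  if (mode == "com") {
    ca <- .com_series(ens, a)
    cb <- .com_series(ens, b)
    vals <- sqrt(rowSums((ca - cb)^2))
  } else {
    vals <- vapply(seq_len(f), function(k) {
      xa <- ens$coords[k, a$indices, , drop = FALSE]
      xb <- ens$coords[k, b$indices, , drop = FALSE]
      xa <- matrix(xa, ncol = 3)
      xb <- matrix(xb, ncol = 3)
      min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
                 2 * xa %*% t(xb)))
    }, numeric(1))
  }
  op_series(paste0("distance_", mode), vals, "nm")
}

#' Principal component analysis of ensemble coordinates
#'
#' Eigendecomposition of the 3A x 3A covariance of the fit-selection
#' coordinates about the ensemble mean. The ensemble should already be
#' superposed on the fit selection. When two systems are compared, run the
#' PCA on their merged ensemble so both are projected in a common eigenbasis.
#'
#' @param ens a `frame_ensemble` (superposed)
#' @param fit an `atom_selection`
#' @param n_components number of components to report projections for
#' @return object of class `pca_result` with `eigenvalues`,
#'   `variance_fraction`, `rotation` (eigenvectors), `center`,
#'   `projections` (F x n_components), `fit_indices`
#' @export
pca_ensemble <- function(ens, fit, n_components = 5) {
  idx <- fit$indices
  f <- n_frames(ens)
  if (f < 2) stop("need at least 2 frames for PCA")
  if (f <= 3 * length(idx))
    warning("fewer frames than 3 x fit atoms; eigenvalues will be noisy")
  x <- matrix(NA_real_, f, 3 * length(idx))
  for (d in 1:3) {
    x[, seq_along(idx) + (d - 1) * length(idx)] <-
      matrix(ens$coords[, idx, d], ncol = length(idx))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  n_components <- min(n_components, length(ev))
  structure(list(
    eigenvalues = ev,
    variance_fraction = ev / sum(ev),
    rotation = pc$rotation,
    center = pc$center,
    projections = pc$x[, seq_len(n_components), drop = FALSE],
    fit_indices = idx
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", length(x$eigenvalues), "components; PC1 fraction",
      sprintf("%.3f\n", x$variance_fraction[1]))
  invisible(x)
}

#' Project an ensemble onto fitted principal components
#' @param pca a `pca_result`
#' @param ens a `frame_ensemble` over the same topology/fit selection
#' @param components component indices (default 1)
#' @return matrix F x length(components)
#' @export
pca_project <- function(pca, ens, components = 1) {
  idx <- pca$fit_indices
  f <- n_frames(ens)
  x <- matrix(NA_real_, f, 3 * length(idx))
  for (d in 1:3) {
    x[, seq_along(idx) + (d - 1) * length(idx)] <-
      matrix(ens$coords[, idx, d], ncol = length(idx))
  }
  sweep(x, 2, pca$center) %*% pca$rotation[, components, drop = FALSE]
}
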