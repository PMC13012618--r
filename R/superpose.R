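# Rigid-body least-squares superposition (Kabsch algorithm).

#' Optimal rotation of `mob` onto `ref` (both centred N x 3 matrices)
#' @return 3 x 3 rotation matrix R such that mob %*% R approximates ref
#' @keywords internal
kabsch_rotation <- function(mob, ref) {
  h <- crossprod(mob, ref)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Rigidly transforms each frame to minimize the RMSD of the fit selection
#' to the same selection in the reference frame (least-squares Kabsch fit).
#' All atoms are moved; only the fit selection defines the transform.
#'
#' @param ens a `frame_ensemble`
#' @param fit an `atom_selection` with at least 3 non-collinear atoms
#' @param reference reference frame index (default 1)
#' @return a new `frame_ensemble`; attribute `"rmsd"` holds the per-frame
#'   post-fit RMSD (nm) of the fit selection
#' @export
superpose <- function(ens, fit, reference = 1) {
  idx <- fit$indices
  if (length(idx) < 3) stop("fit selection needs at least 3 atoms")
  ref <- get_frame(ens, reference)[idx, , drop = FALSE]
  if (.is_degenerate(ref)) stop("fit atoms are collinear or coincident ",
                                "in the reference frame")
  ref_c <- colMeans(ref)
  refc <- sweep(ref, 2, ref_c)
  f <- n_frames(ens)
  out <- array(NA_real_, dim = dim(ens$coords))
  rmsd <- numeric(f)
  for (k in seq_len(f)) {
    xyz <- get_frame(ens, k)
    mob <- xyz[idx, , drop = FALSE]
    mob_c <- colMeans(mob)
    rot <- kabsch_rotation(sweep(mob, 2, mob_c), refc)
    moved <- sweep(xyz, 2, mob_c) %*% rot
    moved <- sweep(moved, 2, ref_c, `+`)
    out[k, , ] <- moved
    d <- moved[idx, , drop = FALSE] - ref
    rmsd[k] <- sqrt(mean(rowSums(d^2)))
  }
  res <- frame_ensemble(ens$topology, out, ens$time)
  attr(res, "rmsd") <- rmsd
  res
}

#' @keywords internal
.is_degenerate <- function(xyz) {
  if (nrow(xyz) < 3) return(TRUE)
  centred <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centred)$d
  sum(sv > 1e-10) < 2
}
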