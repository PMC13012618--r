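# Antiparallel beta-sheet content: RMSD of 6-residue blocks against an
# idealized antiparallel template, accumulated through a rational switching
# function. This is the scalar secondary-structure collective variable used
# to follow beta-strand disruption; it is not a full secondary-structure
# assignment.

#' Idealized antiparallel two-strand template (6 residues, backbone + CB)
#'
#' Two three-residue extended strands with alternating pleat, the second
#' strand rotated 180 degrees about the axis normal to the sheet plane and
#' offset by the canonical inter-strand separation. Atom order is residues
#' 1-3 (first strand, N to C) then 4-6 (second strand, N to C), atoms
#' N, CA, CB, C, O per residue. Coordinates are an idealized synthetic
#' construction, pinned here so scores are reproducible.
#'
#' @return list with `name`, `resid`, `xyz` (18 x 3? no: 30 x 3, nm)
#' @export
antiparallel_template <- function() {
  pitch <- 0.35       # extended-strand rise per residue, nm
  sep <- 0.48         # inter-strand separation, nm
  res_local <- function(pleat) rbind(
    N  = c(0.00,  0.000,  0.000),
    CA = c(0.13,  0.050,  0.040 * pleat),
    CB = c(0.13,  0.160,  0.130 * pleat),
    C  = c(0.26,  0.000,  0.000),
    O  = c(0.26, -0.120,  0.000)
  )
  strand_a <- NULL
  for (r in 0:2) {
    blk <- res_local(pleat = (-1)^r)
    blk[, 1] <- blk[, 1] + r * pitch
    strand_a <- rbind(strand_a, blk)
  }
  # 180-degree rotation about z through the sheet centre, shifted in y
  cx <- 2 * pitch / 2 + 0.13
  strand_b <- strand_a
  strand_b[, 1] <- 2 * cx - strand_a[, 1]
  strand_b[, 2] <- sep - strand_a[, 2]
  xyz <- rbind(strand_a, strand_b)
  rownames(xyz) <- NULL
  list(name = rep(c("N", "CA", "CB", "C", "O"), 6),
       resid = rep(1:6, each = 5),
       xyz = xyz)
}

#' Parameters for the antiparallel beta-content score
#'
#' Defaults follow the common switching-function convention for
#' secondary-structure RMSD variables: r0 = 0.08 nm, exponents 8 and 12,
#' d0 = 0, strands cutoff 1 nm.
#' @param segment1,segment2 residue id vectors of the two strand regions
#' @param r0 switching radius (nm)
#' @param n_exp,m_exp switching exponents (`n_exp < m_exp`)
#' @param d0 switching offset (nm)
#' @param cutoff strands cutoff: maximum distance between window centres
#'   for a block to be scored (nm)
#' @return list of class `beta_params`
#' @export
beta_params <- function(segment1, segment2, r0 = 0.08, n_exp = 8,
                        m_exp = 12, d0 = 0, cutoff = 1.0) {
  if (r0 <= 0) stop("r0 must be positive")
  if (n_exp >= m_exp) stop("n_exp must be smaller than m_exp")
  if (length(segment1) < 3 || length(segment2) < 3)
    stop("each segment needs at least 3 residues")
  structure(list(segment1 = segment1, segment2 = segment2, r0 = r0,
                 n_exp = n_exp, m_exp = m_exp, d0 = d0, cutoff = cutoff),
            class = "beta_params")
}

#' Rational switching function with the x -> 1 limit handled
#' @keywords internal
switch_rational <- function(r, r0, n_exp, m_exp, d0 = 0) {
  x <- (r - d0) / r0
  ifelse(abs(x - 1) < 1e-12, n_exp / m_exp,
         (1 - x^n_exp) / (1 - x^m_exp))
}

#' Antiparallel beta-sheet content of two strand regions
#'
#' For every ordered pair of 3-residue windows (one from each segment)
#' whose backbone centres lie within the strands cutoff, the 6-residue
#' block (N, CA, CB, C, O per residue) is optimally superposed on the
#' antiparallel template and its RMSD r is passed through the switching
#' function (1-((r-d0)/r0)^n)/(1-((r-d0)/r0)^m); contributions are summed
#' into the per-frame score s. Glycine gets a virtual CB constructed from
#' its backbone.
#'
#' @param ens a `frame_ensemble`
#' @param params a [beta_params()]
#' @return an `op_series` (dimensionless)
#' @export
beta_content <- function(ens, params) {
  tpl <- antiparallel_template()
  tpl_xyz <- tpl$xyz
  top <- ens$topology
  block_idx <- function(resids) {
    lapply(resids, function(rid) {
      rows <- which(top$atoms$resid == rid)
      if (length(rows) == 0) stop("residue ", rid, " not in topology")
      sel <- vapply(c("N", "CA", "CB", "C", "O"), function(nm) {
        w <- rows[top$atoms$name[rows] == nm]
        if (length(w) == 0) {
          if (nm == "CB") return(NA_integer_)   # virtual CB later
          stop("residue ", rid, " lacks backbone atom ", nm)
        }
        w[1]
      }, integer(1))
      sel
    })
  }
  wins <- function(seg) {
    lapply(seq_len(length(seg) - 2), function(i) seg[i:(i + 2)])
  }
  w1 <- wins(params$segment1)
  w2 <- wins(params$segment2)
  idx1 <- lapply(w1, block_idx)
  idx2 <- lapply(w2, block_idx)

  frame_block <- function(xyz, idx3) {
    out <- matrix(NA_real_, 0, 3)
    for (res in idx3) {
      blk <- matrix(NA_real_, 5, 3)
      for (a in 1:5) {
        if (is.na(res[a])) {
          blk[a, ] <- .virtual_cb(xyz[res[1], ], xyz[res[2], ],
                                  xyz[res[4], ])
        } else blk[a, ] <- xyz[res[a], ]
      }
      out <- rbind(out, blk)
    }
    out
  }

  f <- n_frames(ens)
  s <- numeric(f)
  for (k in seq_len(f)) {
    xyz <- get_frame(ens, k)
    for (a in seq_along(idx1)) {
      blk1 <- frame_block(xyz, idx1[[a]])
      c1 <- colMeans(blk1)
      for (b in seq_along(idx2)) {
        blk2 <- frame_block(xyz, idx2[[b]])
        if (sqrt(sum((c1 - colMeans(blk2))^2)) > params$cutoff) next
        blk <- rbind(blk1, blk2)
        r <- .fit_rmsd(blk, tpl_xyz)
        s[k] <- s[k] + switch_rational(r, params$r0, params$n_exp,
                                       params$m_exp, params$d0)
      }
    }
  }
  op_series("beta_content", s, "dimensionless")
}

# RMSD after optimal (Kabsch) superposition of blk onto ref.
.fit_rmsd <- function(blk, ref) {
  bc <- sweep(blk, 2, colMeans(blk))
  rc <- sweep(ref, 2, colMeans(ref))
  rot <- kabsch_rotation(bc, rc)
  d <- bc %*% rot - rc
  sqrt(mean(rowSums(d^2)))
}

# Virtual CB for glycine: tetrahedral construction from N, CA, C.
.virtual_cb <- function(n, ca, c) {
  u1 <- (ca - n); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- (ca - c); u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / sqrt(sum(perp^2))
  dir <- bis * cos(0.96) + perp * sin(0.96)
  ca + 0.153 * dir
}
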