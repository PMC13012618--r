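# Typed inter-residue contact detection, per-system frequency tables,
# differential comparison and residue-role classification.
#
# Five interaction types are detected: hydrogen bonds, ionic interactions,
# pi-stacking, pi-cation, and hydrophobic (van der Waals between purely
# hydrophobic residues). Conventions: contacts within a residue are
# dropped, as are backbone-backbone hydrogen bonds between sequence
# neighbours (|i - j| <= 1).

# Bondi van der Waals radii (nm) used for the hydrophobic criterion.
.bondi_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                  P = 0.180)

# Aromatic ring atom names per residue type (6-rings; HIS 5-ring).
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ATP = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# Charged-group atoms.
.cation_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
.anion_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ATP = c("O1A", "O2A", "O3A", "O1B", "O2B", "O3B",
                             "O1G", "O2G", "O3G"))

#' Contact detection criteria
#'
#' Distances in nm, angles in degrees. The hydrogen-bond angle is the
#' donor-H-acceptor angle and must reach at least `hbond_angle` (default
#' 150). The hydrophobic criterion accepts heavy-atom pairs within the sum
#' of their Bondi radii plus `vdw_pad`, restricted to purely hydrophobic
#' residues.
#'
#' @param hbond_dist donor-acceptor heavy-atom cutoff (default 0.35)
#' @param hbond_angle minimum D-H...A angle (default 150)
#' @param ionic_dist anionic-cationic heavy-atom cutoff (default 0.40)
#' @param pi_stack_dist ring-centroid cutoff (default 0.70)
#' @param pi_stack_angle maximum ring-normal angle (default 30)
#' @param pi_cation_dist cation-centroid cutoff (default 0.60)
#' @param pi_cation_angle maximum offset angle from the ring normal
#'   (default 60)
#' @param vdw_pad hydrophobic pad over the Bondi-radius sum (default 0.05)
#' @return list of class `contact_criteria`
#' @export
contact_criteria <- function(hbond_dist = 0.35, hbond_angle = 150,
                             ionic_dist = 0.40, pi_stack_dist = 0.70,
                             pi_stack_angle = 30, pi_cation_dist = 0.60,
                             pi_cation_angle = 60, vdw_pad = 0.05) {
  vals <- c(hbond_dist, ionic_dist, pi_stack_dist, pi_cation_dist)
  if (any(vals <= 0)) stop("all distance thresholds must be positive")
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 ionic_dist = ionic_dist, pi_stack_dist = pi_stack_dist,
                 pi_stack_angle = pi_stack_angle,
                 pi_cation_dist = pi_cation_dist,
                 pi_cation_angle = pi_cation_angle, vdw_pad = vdw_pad),
            class = "contact_criteria")
}

# Static chemistry lookup for a topology: donors (heavy atom + bonded H),
# acceptors, rings, charges, hydrophobic heavies. Donor/acceptor typing is
# rule-based: an N/O/S atom donating through any hydrogen within 0.12 nm in
# the same residue (first frame geometry); acceptors are all oxygens plus
# nitrogens with no bonded hydrogen, plus sulfur.
.contact_chemistry <- function(top, xyz) {
  at <- top$atoms
  n <- nrow(at)
  heavy <- which(at$heavy)
  hyd <- which(!at$heavy)
  donors <- list()
  has_h <- logical(n)
  if (length(hyd)) {
    for (i in heavy) {
      if (!(at$element[i] %in% c("N", "O", "S"))) next
      same_res <- hyd[at$resid[hyd] == at$resid[i] &
                        at$chain[hyd] == at$chain[i]]
      if (!length(same_res)) next
      d <- sqrt(rowSums((xyz[same_res, , drop = FALSE] -
                           matrix(xyz[i, ], length(same_res), 3,
                                  byrow = TRUE))^2))
      hs <- same_res[d < 0.12]
      if (length(hs)) {
        donors[[length(donors) + 1]] <- list(d = i, h = hs)
        has_h[i] <- TRUE
      }
    }
  }
  acceptors <- heavy[(at$element[heavy] == "O") |
                       (at$element[heavy] == "S") |
                       (at$element[heavy] == "N" & !has_h[heavy])]
  rings <- list()
  for (key in split(seq_len(n), paste(at$chain, at$resid))) {
    rn <- at$resname[key[1]]
    if (!rn %in% names(.ring_atoms)) next
    ra <- key[match(.ring_atoms[[rn]], at$name[key])]
    if (anyNA(ra)) next
    rings[[length(rings) + 1]] <- ra
  }
  cat_atoms <- integer(0)
  an_atoms <- integer(0)
  for (i in heavy) {
    rn <- at$resname[i]
    if (rn %in% names(.cation_atoms) && at$name[i] %in% .cation_atoms[[rn]])
      cat_atoms <- c(cat_atoms, i)
    if (rn %in% names(.anion_atoms) && at$name[i] %in% .anion_atoms[[rn]])
      an_atoms <- c(an_atoms, i)
    if (at$element[i] %in% c("MG", "NA", "K", "CA", "ZN") &&
        !at$resname[i] %in% .protein_resnames)
      cat_atoms <- c(cat_atoms, i)
  }
  hydro <- heavy[at$hydrophobic[heavy]]
  list(donors = donors, acceptors = acceptors, rings = rings,
       cations = cat_atoms, anions = an_atoms, hydrophobic = hydro,
       any_h = length(hyd) > 0)
}

#' Detect typed contacts in one frame
#'
#' @param ens a `frame_ensemble`
#' @param frame frame index
#' @param criteria a [contact_criteria()]
#' @return data.frame with columns `i`, `j` (residue ids, `i < j`) and
#'   `type`; one row per residue pair and satisfied type
#' @export
detect_contacts <- function(ens, frame = 1, criteria = contact_criteria()) {
  chem <- .contact_chemistry(ens$topology, get_frame(ens, 1))
  if (!chem$any_h)
    warning("no hydrogens in topology: hydrogen-bond detection disabled")
  .detect_frame(ens$topology, get_frame(ens, frame), chem, criteria)
}

.detect_frame <- function(top, xyz, chem, criteria) {
  at <- top$atoms
  res_of <- at$resid
  out_i <- integer(0); out_j <- integer(0); out_t <- character(0)
  add <- function(ai, aj, type) {
    ri <- res_of[ai]; rj <- res_of[aj]
    if (ri == rj) return()
    out_i <<- c(out_i, min(ri, rj))
    out_j <<- c(out_j, max(ri, rj))
    out_t <<- c(out_t, type)
  }
  dist2 <- function(a, b) sum((xyz[a, ] - xyz[b, ])^2)

  # hydrogen bonds
  for (dn in chem$donors) {
    for (ac in chem$acceptors) {
      if (res_of[ac] == res_of[dn$d]) next
      if (dist2(dn$d, ac) > criteria$hbond_dist^2) next
      # neighbour backbone-backbone exclusion
      if (abs(res_of[ac] - res_of[dn$d]) <= 1 &&
          at$backbone[ac] && at$backbone[dn$d]) next
      ok <- FALSE
      for (h in dn$h) {
        v1 <- xyz[dn$d, ] - xyz[h, ]
        v2 <- xyz[ac, ] - xyz[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= criteria$hbond_angle) { ok <- TRUE; break }
      }
      if (ok) add(dn$d, ac, "hbond")
    }
  }
  # ionic
  for (a in chem$anions) for (c_ in chem$cations) {
    if (res_of[a] != res_of[c_] &&
        dist2(a, c_) <= criteria$ionic_dist^2) add(a, c_, "ionic")
  }
  # pi-stacking
  ring_geo <- lapply(chem$rings, function(r) {
    pts <- xyz[r, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    list(ctr = ctr, normal = sv$v[, 3], res = res_of[r[1]], atoms = r)
  })
  nr <- length(ring_geo)
  if (nr >= 2) {
    for (a in 1:(nr - 1)) for (b in (a + 1):nr) {
      ra <- ring_geo[[a]]; rb <- ring_geo[[b]]
      if (ra$res == rb$res) next
      if (sum((ra$ctr - rb$ctr)^2) > criteria$pi_stack_dist^2) next
      cosang <- abs(sum(ra$normal * rb$normal))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang <= criteria$pi_stack_angle)
        add(ra$atoms[1], rb$atoms[1], "pi_stack")
    }
  }
  # pi-cation
  for (rg in ring_geo) {
    for (c_ in chem$cations) {
      if (res_of[c_] == rg$res) next
      v <- xyz[c_, ] - rg$ctr
      if (sum(v^2) > criteria$pi_cation_dist^2) next
      cosang <- abs(sum(v * rg$normal)) / sqrt(sum(v^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang <= criteria$pi_cation_angle)
        add(rg$atoms[1], c_, "pi_cation")
    }
  }
  # hydrophobic
  hy <- chem$hydrophobic
  if (length(hy) >= 2) {
    rad <- .bondi_radii[at$element[hy]]
    rad[is.na(rad)] <- 0.17
    for (a in seq_along(hy)[-length(hy)]) {
      for (b in (a + 1):length(hy)) {
        ai <- hy[a]; bi <- hy[b]
        if (res_of[ai] == res_of[bi]) next
        cut <- rad[a] + rad[b] + criteria$vdw_pad
        if (dist2(ai, bi) <= cut^2) add(ai, bi, "hydrophobic")
      }
    }
  }
  if (!length(out_i))
    return(data.frame(i = integer(0), j = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  unique(data.frame(i = out_i, j = out_j, type = out_t,
                    stringsAsFactors = FALSE))
}

#' Per-residue-pair contact frequencies over an ensemble
#'
#' @param ens a `frame_ensemble`
#' @param criteria a [contact_criteria()]
#' @return data.frame of class `contact_table` with `i`, `j`, `type`,
#'   `count`, `n_frames`, `freq` (exact frame fraction)
#' @export
contact_frequencies <- function(ens, criteria = contact_criteria()) {
  chem <- .contact_chemistry(ens$topology, get_frame(ens, 1))
  if (!chem$any_h)
    warning("no hydrogens in topology: hydrogen-bond detection disabled")
  f <- n_frames(ens)
  counts <- new.env(parent = emptyenv())
  for (k in seq_len(f)) {
    d <- .detect_frame(ens$topology, get_frame(ens, k), chem, criteria)
    if (!nrow(d)) next
    keys <- paste(d$i, d$j, d$type, sep = "\r")
    for (key in keys) {
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    out <- data.frame(i = integer(0), j = integer(0), type = character(0),
                      count = integer(0), n_frames = integer(0),
                      freq = numeric(0), stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    out <- data.frame(i = as.integer(parts[, 1]),
                      j = as.integer(parts[, 2]),
                      type = parts[, 3],
                      count = vapply(keys, function(k) counts[[k]],
                                     integer(1)),
                      n_frames = f, stringsAsFactors = FALSE)
    out$freq <- out$count / out$n_frames
    out <- out[order(out$i, out$j, out$type), ]
    rownames(out) <- NULL
  }
  class(out) <- c("contact_table", class(out))
  out
}

#' Differential contact table between two systems
#'
#' Union of the two tables' keys (absent keys count as frequency 0); the
#' difference is expressed in percentage points and flagged when its
#' magnitude exceeds `threshold_pp` (default 40).
#'
#' @param a,b `contact_table`s over the same residue numbering
#' @param threshold_pp flagging threshold in percentage points
#' @return data.frame of class `differential_table` with `i`, `j`, `type`,
#'   `f_a`, `f_b`, `delta_pp` (`= 100 (f_b - f_a)`), `flagged`
#' @export
differential_contacts <- function(a, b, threshold_pp = 40) {
  key <- function(t) paste(t$i, t$j, t$type, sep = "\r")
  ka <- key(a); kb <- key(b)
  all_keys <- union(ka, kb)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  f_a <- a$freq[match(all_keys, ka)]
  f_b <- b$freq[match(all_keys, kb)]
  f_a[is.na(f_a)] <- 0
  f_b[is.na(f_b)] <- 0
  out <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                    type = parts[, 3], f_a = f_a, f_b = f_b,
                    delta_pp = 100 * (f_b - f_a),
                    stringsAsFactors = FALSE)
  out$flagged <- abs(out$delta_pp) > threshold_pp
  out <- out[order(out$i, out$j, out$type), ]
  rownames(out) <- NULL
  attr(out, "threshold_pp") <- threshold_pp
  class(out) <- c("differential_table", class(out))
  out
}

#' Classify residues by ligand binding and inter-lobe bridging
#'
#' A residue is ligand-binding if any contact type links it to a ligand
#' residue for at least `threshold` of the trajectory (default 50%), and
#' at the inter-lobe interface if any contact links it to a residue of the
#' opposite lobe at the same persistence.
#'
#' @param table a `contact_table`
#' @param ligand_resids residue ids of the ligand
#' @param lobe_map named vector residue id -> lobe label (must cover all
#'   protein residues in the table)
#' @param threshold persistence threshold (fraction, default 0.5)
#' @return data.frame `resid`, `role` (`"ligand-binding"`,
#'   `"interlobe-interface"`, `"both"`, `"neither"`)
#' @export
classify_residues <- function(table, ligand_resids, lobe_map,
                              threshold = 0.5) {
  prot <- sort(unique(c(table$i, table$j)))
  prot <- setdiff(prot, ligand_resids)
  missing_map <- setdiff(prot, as.integer(names(lobe_map)))
  if (length(missing_map))
    stop("residues absent from lobe_map: ",
         paste(missing_map, collapse = ", "))
  lobe <- function(r) lobe_map[as.character(r)]
  role <- vapply(prot, function(r) {
    rows <- table[table$i == r | table$j == r, , drop = FALSE]
    partner <- ifelse(rows$i == r, rows$j, rows$i)
    lig <- any(rows$freq >= threshold & partner %in% ligand_resids)
    cross <- any(rows$freq >= threshold & !(partner %in% ligand_resids) &
                   lobe(partner) != lobe(r))
    if (lig && cross) "both"
    else if (lig) "ligand-binding"
    else if (cross) "interlobe-interface"
    else "neither"
  }, character(1))
  data.frame(resid = prot, role = role, stringsAsFactors = FALSE)
}

#' Export a differential table as chord-diagram JSON (plus a TSV twin)
#'
#' The JSON dialect mirrors the flare/chord-diagram convention: an `edges`
#' array with per-edge frequencies and differences, and a `nodes` array
#' with optional role annotations.
#'
#' @param diff a `differential_table`
#' @param roles optional classification from [classify_residues()]
#' @param path output path for the JSON; the TSV twin replaces the
#'   extension with `.tsv`
#' @param flagged_only keep only flagged edges
#' @return `path`, invisibly
#' @export
export_chord <- function(diff, path, roles = NULL, flagged_only = FALSE) {
  edges <- diff
  if (flagged_only) edges <- edges[edges$flagged, , drop = FALSE]
  edge_list <- lapply(seq_len(nrow(edges)), function(r) {
    list(name1 = as.character(edges$i[r]), name2 = as.character(edges$j[r]),
         type = edges$type[r], f_a = edges$f_a[r], f_b = edges$f_b[r],
         delta_pp = edges$delta_pp[r], flagged = edges$flagged[r])
  })
  nodes <- sort(unique(c(edges$i, edges$j)))
  node_list <- lapply(nodes, function(nd) {
    role <- if (!is.null(roles) && nd %in% roles$resid)
      roles$role[roles$resid == nd] else "unannotated"
    list(name = as.character(nd), role = role)
  })
  jsonlite::write_json(list(edges = edge_list, nodes = node_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv <- sub("\\.[A-Za-z]+$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(as.data.frame(edges), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
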