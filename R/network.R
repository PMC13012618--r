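# Dynamic network construction: node maps (C-alpha anchors + ligand
# pseudo-nodes), persistence-gated contact edges, and generalized
# correlation (GC) edge weights from k-nearest-neighbour mutual
# information between node fluctuation vectors.

# ATP-like ligand split: purine-ring heavies anchor at N1; phosphates and
# ribose anchor at the terminal (gamma) phosphorus.
.atp_ring_heavy <- c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8",
                     "N9")

#' Assign network nodes from a topology
#'
#' One node per protein residue, anchored at its C-alpha and owning the
#' residue's heavy atoms. Ligand selections become pseudo-nodes: a
#' single-atom selection (e.g. a metal ion) is one node; an ATP-like
#' residue is split into two nodes (purine ring anchored at N1, phosphates
#' plus ribose anchored at the terminal phosphorus); any other ligand
#' becomes one node anchored at its first heavy atom.
#'
#' @param top a `topology`
#' @param protein an `atom_selection` covering the protein residues (each
#'   must contain a CA atom)
#' @param ligands optional named list of `atom_selection`s
#' @return object of class `node_map`: list of nodes with `label`,
#'   `atoms` (heavy-atom indices for contact tests), `anchor` (atom index
#'   for the fluctuation vector)
#' @export
assign_nodes <- function(top, protein, ligands = NULL) {
  at <- top$atoms
  nodes <- list()
  pidx <- protein$indices
  for (rid in unique(at$resid[pidx])) {
    rows <- pidx[at$resid[pidx] == rid]
    ca <- rows[at$name[rows] == "CA"]
    if (length(ca) == 0) stop("residue ", rid, " has no CA atom")
    nodes[[length(nodes) + 1]] <- list(
      label = as.character(rid),
      atoms = rows[at$heavy[rows]],
      anchor = ca[1])
  }
  for (nm in names(ligands)) {
    rows <- ligands[[nm]]$indices
    heavy <- rows[at$heavy[rows]]
    if (!length(heavy)) stop("ligand '", nm, "' has no heavy atoms")
    resname <- at$resname[heavy[1]]
    if (length(heavy) == 1) {
      nodes[[length(nodes) + 1]] <- list(label = nm, atoms = heavy,
                                         anchor = heavy)
    } else if (resname == "ATP" ||
               all(c("N1", "PG") %in% at$name[heavy])) {
      ring <- heavy[at$name[heavy] %in% .atp_ring_heavy]
      rest <- setdiff(heavy, ring)
      n1 <- heavy[at$name[heavy] == "N1"]
      pg <- heavy[at$name[heavy] == "PG"]
      if (!length(n1) || !length(pg))
        stop("ATP-like ligand '", nm, "' lacks N1 or PG atoms")
      nodes[[length(nodes) + 1]] <- list(label = paste0(nm, ":ring"),
                                         atoms = ring, anchor = n1[1])
      nodes[[length(nodes) + 1]] <- list(label = paste0(nm, ":pgamma"),
                                         atoms = rest, anchor = pg[1])
    } else {
      nodes[[length(nodes) + 1]] <- list(label = nm, atoms = heavy,
                                         anchor = heavy[1])
    }
  }
  # partition check: no heavy atom in two nodes
  all_atoms <- unlist(lapply(nodes, `[[`, "atoms"))
  if (anyDuplicated(all_atoms))
    stop("node atom sets overlap: atom ",
         all_atoms[duplicated(all_atoms)][1])
  structure(nodes, class = "node_map")
}

#' @export
print.node_map <- function(x, ...) {
  cat("node_map:", length(x), "nodes\n")
  invisible(x)
}

#' Persistence-gated contact edges between nodes
#'
#' Two nodes are connected if the minimum distance between their heavy
#' atoms stays within `cutoff` for at least a `persistence` fraction of
#' frames.
#'
#' @param ens a `frame_ensemble`
#' @param nodes a `node_map`
#' @param cutoff heavy-atom distance cutoff (nm, default 0.45)
#' @param persistence minimum contact fraction (default 0.75)
#' @return data.frame `a`, `b` (node indices, a < b), `contact_fraction`
#' @export
build_edges <- function(ens, nodes, cutoff = 0.45, persistence = 0.75) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (persistence <= 0 || persistence > 1)
    stop("persistence must be in (0, 1]")
  nn <- length(nodes)
  f <- n_frames(ens)
  # mean positions for candidate pruning
  centers <- t(vapply(nodes, function(nd) {
    colMeans(matrix(apply(ens$coords[, nd$atoms, , drop = FALSE],
                          3, mean), ncol = 3))
  }, numeric(3)))
  spread <- max(vapply(seq_len(nn), function(i) {
    xs <- matrix(ens$coords[, nodes[[i]]$atoms, , drop = FALSE],
                 nrow = f)
    max(abs(sweep(matrix(xs, ncol = 3), 2,
                  centers[i, ])))
  }, numeric(1)))
  slack <- cutoff + 4 * spread
  out_a <- integer(0); out_b <- integer(0); out_f <- numeric(0)
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      if (sqrt(sum((centers[i, ] - centers[j, ])^2)) > slack) next
      ai <- nodes[[i]]$atoms; aj <- nodes[[j]]$atoms
      mind2 <- rep(Inf, f)
      for (a in ai) for (b in aj) {
        d2 <- (ens$coords[, a, 1] - ens$coords[, b, 1])^2 +
          (ens$coords[, a, 2] - ens$coords[, b, 2])^2 +
          (ens$coords[, a, 3] - ens$coords[, b, 3])^2
        mind2 <- pmin(mind2, d2)
      }
      frac <- mean(mind2 <= cutoff^2)
      if (frac >= persistence) {
        out_a <- c(out_a, i); out_b <- c(out_b, j)
        out_f <- c(out_f, frac)
      }
    }
  }
  data.frame(a = out_a, b = out_b, contact_fraction = out_f)
}

#' Generalized correlation between node pairs
#'
#' For each requested pair, the mutual information I between the two 3-D
#' anchor displacement series (position minus its time mean) is estimated
#' with the Kraskov k-nearest-neighbour estimator (Chebyshev metric) and
#' mapped to GC = sqrt(1 - exp(-2 I / 3)), clipped to [0, 1 - 1e-12].
#' For jointly Gaussian fluctuations with per-dimension correlation rho
#' this recovers GC = |rho|.
#'
#' @param ens a `frame_ensemble` (superposed)
#' @param nodes a `node_map`
#' @param pairs two-column matrix/data.frame of node indices
#' @param k neighbour count of the MI estimator (default 7)
#' @return numeric vector of GC values, one per pair row
#' @export
generalized_correlation <- function(ens, nodes, pairs, k = 7) {
  f <- n_frames(ens)
  if (f < 500)
    warning("fewer than 500 frames: GC estimates will be noisy")
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  used <- sort(unique(as.vector(pairs)))
  disp <- list()
  for (i in used) {
    x <- matrix(ens$coords[, nodes[[i]]$anchor, ], ncol = 3)
    x <- sweep(x, 2, colMeans(x))
    if (all(apply(x, 2, stats::sd) < 1e-12))
      stop("node '", nodes[[i]]$label, "' has zero variance: GC undefined")
    disp[[as.character(i)]] <- x
  }
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    mi <- ksg_mi(disp[[as.character(i)]], disp[[as.character(j)]],
                 as.integer(k))
    gc_val <- sqrt(max(0, 1 - exp(-2 * mi / 3)))
    min(gc_val, 1 - 1e-12)
  }, numeric(1))
}

#' Assemble a dynamic network
#'
#' @param nodes a `node_map`
#' @param edges edge data.frame from [build_edges()]
#' @param gc GC weight per edge (same order as `edges`)
#' @param params list of build parameters recorded on the object
#' @return object of class `dynamic_network`; edges carry `gc` and the
#'   path distance `d = -log(gc)`
#' @export
dynamic_network <- function(nodes, edges, gc, params = list()) {
  if (nrow(edges) != length(gc)) stop("one GC value per edge required")
  if (any(gc < 0 | gc >= 1)) stop("GC values must lie in [0, 1)")
  edges$gc <- gc
  # floor before the log: a physically present edge with a vanishing GC
  # estimate keeps a finite (heavily penalized) path distance
  edges$d <- -log(pmin(pmax(gc, 1e-6), 1 - 1e-12))
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("dynamic_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' One-call network construction from an ensemble
#'
#' Builds edges on the (merged) ensemble, then weights them with GC
#' computed either on the same ensemble or, in the two-pass mode, on each
#' analysis window separately while keeping the merged-topology edges.
#'
#' @param ens a `frame_ensemble` (merged data)
#' @param nodes a `node_map`
#' @param cutoff,persistence edge rule parameters
#' @param k MI estimator neighbour count
#' @param windows optional list of `frame_ensemble`s; when given, a list
#'   of networks (one per window, shared edge topology) is returned
#' @return a `dynamic_network`, or a list of them in windowed mode
#' @export
network_from_ensemble <- function(ens, nodes, cutoff = 0.45,
                                  persistence = 0.75, k = 7,
                                  windows = NULL) {
  edges <- build_edges(ens, nodes, cutoff, persistence)
  params <- list(cutoff = cutoff, persistence = persistence, k = k)
  if (is.null(windows)) {
    gc_vals <- generalized_correlation(ens, nodes, edges[, c("a", "b")], k)
    return(dynamic_network(nodes, edges, gc_vals, params))
  }
  lapply(windows, function(w) {
    gc_vals <- generalized_correlation(w, nodes, edges[, c("a", "b")], k)
    dynamic_network(nodes, edges, gc_vals, params)
  })
}

# igraph view of a dynamic network (vertex name = node index as character).
.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$a),
               to = as.character(net$edges$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_along(net$nodes))))
  igraph::E(g)$gc <- net$edges$gc
  igraph::E(g)$d <- net$edges$d
  g
}

#' Export a network as a weighted edge-list TSV
#' @param net a `dynamic_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  labels <- vapply(net$nodes, `[[`, character(1), "label")
  utils::write.table(
    data.frame(i = labels[net$edges$a], j = labels[net$edges$b],
               gc = net$edges$gc, d = net$edges$d),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
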