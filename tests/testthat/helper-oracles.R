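# Independent oracle implementations used to cross-check the package.
# These deliberately use different formulations / libraries than the code
# under test.

# Dihedral via plane normals and acos, signed by a triple product
# (different route than the package's atan2 form).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(max(-1, min(1, cosphi))) * 180 / pi
  if (sum(cx(n1, n2) * b2) < 0) phi <- -phi
  phi
}

# Brute-force RMSD after optimal superposition, via bio3d's least-squares
# rotation (independent of the package's SVD Kabsch).
oracle_fit_rmsd <- function(mob, ref) {
  mxyz <- as.vector(t(mob))
  rxyz <- as.vector(t(ref))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = rxyz, mobile = matrix(mxyz, nrow = 1)))
  sqrt(mean((fitted - rxyz)^2) * 3)
}

# All simple paths between two nodes of a small weighted graph
# (edge list: data.frame a, b, w), by exhaustive DFS.
oracle_all_simple_paths <- function(edges, n, from, to) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]; w <- edges$w[r]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  paths <- list(); costs <- numeric(0)
  walk <- function(node, visited, cost) {
    if (node == to) {
      paths[[length(paths) + 1]] <<- visited
      costs[length(costs) + 1] <<- cost
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), cost + nb[r, 2])
    }
  }
  walk(from, from, 0)
  ord <- order(costs)
  list(paths = paths[ord], costs = costs[ord])
}

# Random connected weighted graph on n nodes (spanning tree + extra edges).
random_weighted_graph <- function(n, extra = n, seed) {
  set.seed(seed)
  edges <- data.frame(a = integer(0), b = integer(0), w = numeric(0))
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    edges <- rbind(edges, data.frame(a = u, b = v, w = runif(1, 0.1, 2)))
  }
  for (k in seq_len(extra)) {
    uv <- sample.int(n, 2)
    u <- min(uv); v <- max(uv)
    if (any(edges$a == u & edges$b == v)) next
    edges <- rbind(edges, data.frame(a = u, b = v, w = runif(1, 0.1, 2)))
  }
  edges
}

# Wrap an edge list into a dynamic_network with the given distances d
# (gc chosen to reproduce d = -log(gc)).
net_from_edgelist <- function(edges, n) {
  nodes <- lapply(seq_len(n), function(i)
    list(label = as.character(i), atoms = i, anchor = i))
  class(nodes) <- "node_map"
  gc_vals <- exp(-edges$w)
  dynamic_network(nodes,
                  data.frame(a = edges$a, b = edges$b,
                             contact_fraction = 1),
                  gc_vals)
}

# Small helper: bead-chain ensemble with explicit coordinates per frame.
bead_ensemble <- function(pos_list) {
  n <- nrow(pos_list[[1]])
  top <- topology(name = rep("CA", n), resid = seq_len(n),
                  resname = rep("ALA", n), element = rep("C", n))
  coords <- array(NA_real_, dim = c(length(pos_list), n, 3))
  for (f in seq_along(pos_list)) coords[f, , ] <- pos_list[[f]]
  frame_ensemble(top, coords)
}
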