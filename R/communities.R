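# Community structure of the dynamic network (Louvain modularity on GC
# weights) and betweenness centrality, aggregated to community pairs.

#' Louvain community detection on GC edge weights
#'
#' Modularity optimization with the GC coefficients as edge weights.
#' Communities holding less than `discard_below` of all nodes (default 1%)
#' are moved to a discarded list. The result is deterministic under the
#' given seed.
#'
#' @param net a `dynamic_network`
#' @param seed RNG seed for the (order-dependent) Louvain heuristic
#' @param discard_below discard threshold as a fraction of all nodes
#' @param resolution Louvain resolution parameter
#' @return object of class `community_partition`: `membership` (named by
#'   node index; `NA` for discarded nodes), `sizes`, `discarded` (node
#'   indices), `modularity`
#' @export
detect_communities <- function(net, seed = 0, discard_below = 0.01,
                               resolution = 1) {
  if (length(net$nodes) == 0) stop("empty network")
  g <- .as_igraph(net)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$gc,
                                resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- as.integer(memb[as.character(seq_along(net$nodes))])
  n <- length(net$nodes)
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < discard_below * n])
  discarded <- which(memb %in% small)
  memb[memb %in% small] <- NA_integer_
  # relabel retained communities 0, 1, 2, ... by decreasing size
  keep <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(keep) - 1L, names(keep))
  memb <- ifelse(is.na(memb), NA_integer_,
                 relab[as.character(memb)])
  names(memb) <- seq_len(n)
  structure(list(membership = memb,
                 sizes = table(memb),
                 discarded = discarded,
                 modularity = igraph::modularity(cl)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", length(x$sizes), "communities,",
      length(x$discarded), "discarded node(s)\n")
  invisible(x)
}

#' Betweenness centrality per node and per community pair
#'
#' Node betweenness over weighted shortest paths (weights d = -log GC),
#' reported as the fraction of all node pairs whose shortest path passes
#' through the node. Community-pair strength aggregates the edge
#' betweenness of edges crossing the pair (or, with `method = "node"`, the
#' node betweenness of the endpoints) and is normalized to a maximum of 1.
#'
#' @param net a `dynamic_network`
#' @param partition a `community_partition`
#' @param method `"edge"` (default) or `"node"` aggregation
#' @return list with `node_betweenness` (fractions), `community_matrix`
#'   (symmetric, max 1), `edge_betweenness`
#' @export
community_betweenness <- function(net, partition, method = c("edge",
                                                             "node")) {
  method <- match.arg(method)
  g <- .as_igraph(net)
  n <- length(net$nodes)
  bt <- igraph::betweenness(g, weights = igraph::E(g)$d, directed = FALSE)
  node_bt <- bt[as.character(seq_len(n))] / ((n - 1) * (n - 2) / 2)
  eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$d,
                                 directed = FALSE)
  memb <- partition$membership
  comms <- sort(unique(memb[!is.na(memb)]))
  m <- matrix(0, length(comms), length(comms),
              dimnames = list(comms, comms))
  for (r in seq_len(nrow(net$edges))) {
    ca <- memb[net$edges$a[r]]
    cb <- memb[net$edges$b[r]]
    if (is.na(ca) || is.na(cb) || ca == cb) next
    w <- if (method == "edge") eb[r]
         else node_bt[net$edges$a[r]] + node_bt[net$edges$b[r]]
    ia <- match(ca, comms); ib <- match(cb, comms)
    m[ia, ib] <- m[ia, ib] + w
    m[ib, ia] <- m[ia, ib]
  }
  if (max(m) > 0) m <- m / max(m)
  list(node_betweenness = node_bt, community_matrix = m,
       edge_betweenness = eb)
}
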