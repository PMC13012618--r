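# Allosteric pathway tracing on the dynamic network: Floyd-Warshall
# all-pairs shortest paths on d = -log(GC) edge distances, plus ranked
# suboptimal simple paths and per-node occurrence frequencies.

#' Floyd-Warshall all-pairs shortest paths
#'
#' @param dmat symmetric distance matrix (`Inf` where no edge, 0 diagonal)
#' @return list with `dist` (shortest-path distances) and `nxt`
#'   (successor matrix for path reconstruction; `NA` where unreachable)
#' @export
floyd_warshall <- function(dmat) {
  n <- nrow(dmat)
  dist <- dmat
  nxt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(dist[i, j])) nxt[i, j] <- j
  }
  for (k in seq_len(n)) {
    dk <- dist[, k]
    for (i in seq_len(n)) {
      if (!is.finite(dk[i])) next
      through <- dk[i] + dist[k, ]
      better <- through < dist[i, ]
      if (any(better)) {
        dist[i, better] <- through[better]
        nxt[i, better] <- nxt[i, k]
      }
    }
  }
  list(dist = dist, nxt = nxt)
}

# Reconstruct the i -> j path from a successor matrix.
.fw_path <- function(nxt, i, j) {
  if (is.na(nxt[i, j])) return(NULL)
  path <- i
  while (i != j) {
    i <- nxt[i, j]
    path <- c(path, i)
  }
  path
}

# Resolve a node reference (index or label) to an index.
.node_index <- function(net, node) {
  if (is.numeric(node)) {
    idx <- as.integer(node)
    if (idx < 1 || idx > length(net$nodes)) stop("node index out of range")
    return(idx)
  }
  labels <- vapply(net$nodes, `[[`, character(1), "label")
  idx <- match(as.character(node), labels)
  if (is.na(idx)) stop("unknown node '", node, "'")
  idx
}

# Dense distance matrix of a network.
.net_dmat <- function(net) {
  n <- length(net$nodes)
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  for (r in seq_len(nrow(net$edges))) {
    a <- net$edges$a[r]; b <- net$edges$b[r]
    dmat[a, b] <- dmat[b, a] <- net$edges$d[r]
  }
  dmat
}

#' Optimal (minimum total distance) path between two nodes
#'
#' Shortest path on the edge distances d = -log(GC) computed with
#' Floyd-Warshall; the all-pairs solution is attached for reuse.
#'
#' @param net a `dynamic_network`
#' @param source,sink node labels or indices (distinct)
#' @return list with `path` (node indices; `NULL` when disconnected),
#'   `labels`, `cost`, `connected`, and `fw` (the all-pairs solution)
#' @export
optimal_path <- function(net, source, sink) {
  s <- .node_index(net, source)
  t <- .node_index(net, sink)
  if (s == t) stop("source and sink must differ")
  fw <- floyd_warshall(.net_dmat(net))
  if (!is.finite(fw$dist[s, t])) {
    return(list(path = NULL, labels = NULL, cost = Inf, connected = FALSE,
                fw = fw))
  }
  p <- .fw_path(fw$nxt, s, t)
  labels <- vapply(net$nodes, `[[`, character(1), "label")
  list(path = p, labels = labels[p], cost = fw$dist[s, t],
       connected = TRUE, fw = fw)
}

#' Optimal plus ranked suboptimal paths with node occurrence frequencies
#'
#' The `count` next-shortest simple paths after the optimal one (Yen's
#' k-shortest simple paths on the same distances). The per-node occurrence
#' frequency is the fraction of the returned path set (optimal included)
#' containing that node.
#'
#' @param net a `dynamic_network`
#' @param source,sink node labels or indices
#' @param count number of suboptimal paths (default 20)
#' @return object of class `path_set`: `paths` (list of node-index
#'   vectors, optimal first), `costs` (non-decreasing), `occurrence`
#'   (named per-node frequency over the set), `exhausted` (TRUE when the
#'   graph holds fewer simple paths than requested), `source`, `sink`
#' @export
suboptimal_paths <- function(net, source, sink, count = 20) {
  s <- .node_index(net, source)
  t <- .node_index(net, sink)
  if (s == t) stop("source and sink must differ")
  g <- .as_igraph(net)
  ks <- igraph::k_shortest_paths(g, from = as.character(s),
                                 to = as.character(t),
                                 k = count + 1,
                                 weights = igraph::E(g)$d)
  paths <- lapply(ks$vpaths, function(v)
    as.integer(igraph::as_ids(v)))
  if (length(paths) == 0)
    return(structure(list(paths = list(), costs = numeric(0),
                          occurrence = numeric(0), exhausted = TRUE,
                          source = s, sink = t), class = "path_set"))
  dmat <- .net_dmat(net)
  costs <- vapply(paths, function(p)
    sum(dmat[cbind(p[-length(p)], p[-1])]), numeric(1))
  ord <- order(costs)
  paths <- paths[ord]
  costs <- costs[ord]
  n <- length(net$nodes)
  occ <- numeric(n)
  for (p in paths) occ[p] <- occ[p] + 1
  occ <- occ / length(paths)
  names(occ) <- vapply(net$nodes, `[[`, character(1), "label")
  structure(list(paths = paths, costs = costs, occurrence = occ,
                 exhausted = length(paths) < count + 1,
                 source = s, sink = t),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat("path_set:", length(x$paths), "paths, costs",
      sprintf("%.3f-%.3f", min(x$costs), max(x$costs)),
      if (x$exhausted) "(exhausted)" else "", "\n")
  invisible(x)
}

#' Export a path set as JSON
#' @param ps a `path_set`
#' @param net the `dynamic_network` it was computed on (for labels)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_path_set <- function(ps, net, path) {
  labels <- vapply(net$nodes, `[[`, character(1), "label")
  jsonlite::write_json(list(
    source = labels[ps$source], sink = labels[ps$sink],
    paths = lapply(seq_along(ps$paths), function(i)
      list(rank = i, cost = ps$costs[i],
           nodes = labels[ps$paths[[i]]])),
    occurrence = as.list(ps$occurrence[ps$occurrence > 0])
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
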