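# Sensitivity of network topology and path routing to the edge-rule
# parameters, summarized with Jaccard indices against the reference
# parameter pair.

#' Jaccard index of two sets
#' @param a,b vectors treated as sets
#' @return `|a intersect b| / |a union b|`; 1 when both sets are empty
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

# Canonical string keys for undirected edges / path connections.
.edge_keys <- function(pairs) {
  apply(cbind(pmin(pairs[, 1], pairs[, 2]),
              pmax(pairs[, 1], pairs[, 2])), 1, paste, collapse = "-")
}

.path_connections <- function(paths) {
  out <- character(0)
  for (p in paths) {
    if (length(p) < 2) next
    out <- c(out, .edge_keys(cbind(p[-length(p)], p[-1])))
  }
  unique(out)
}

#' Scan edge-rule parameters and compare path routing to the reference
#'
#' Rebuilds the network and the optimal + suboptimal path set at every
#' (cutoff, persistence) grid point, then reports the Jaccard similarity
#' to the reference point for (i) the edge set, (ii) the set of unique
#' path residues, and (iii) the set of unique path connections, along
#' with per-node occurrence frequencies across grid points. GC weights
#' are computed once per node pair and reused across the grid.
#'
#' @param ens a `frame_ensemble`
#' @param nodes a `node_map`
#' @param source,sink path endpoints (labels or indices)
#' @param cutoffs distance cutoffs to scan (nm); must include `reference[1]`
#' @param persistences persistence fractions to scan; must include
#'   `reference[2]`
#' @param reference reference parameter pair (default `c(0.45, 0.75)`)
#' @param count suboptimal path count per grid point
#' @param k MI estimator neighbour count
#' @return list with `grid` (per-point data.frame: cutoff, persistence,
#'   jaccard_edges, jaccard_residues, jaccard_connections, connected),
#'   `occurrence` (node x grid-point matrix), `reference`
#' @export
sensitivity_scan <- function(ens, nodes, source, sink,
                             cutoffs = c(0.42, 0.45, 0.48),
                             persistences = c(0.65, 0.75, 0.85),
                             reference = c(0.45, 0.75),
                             count = 20, k = 7) {
  if (!any(abs(cutoffs - reference[1]) < 1e-9) ||
      !any(abs(persistences - reference[2]) < 1e-9))
    stop("the reference parameters must be part of the scan grid")
  gc_cache <- new.env(parent = emptyenv())
  cached_gc <- function(pairs) {
    keys <- paste(pairs[, 1], pairs[, 2], sep = "-")
    need <- !vapply(keys, function(kk) !is.null(gc_cache[[kk]]),
                    logical(1))
    if (any(need)) {
      vals <- generalized_correlation(ens, nodes,
                                      pairs[need, , drop = FALSE], k)
      for (ii in seq_along(vals)) gc_cache[[keys[need][ii]]] <- vals[ii]
    }
    vapply(keys, function(kk) gc_cache[[kk]], numeric(1))
  }
  run_point <- function(cutoff, persistence) {
    edges <- build_edges(ens, nodes, cutoff, persistence)
    if (nrow(edges) == 0)
      return(list(net = NULL, ps = NULL, edges = edges))
    net <- dynamic_network(nodes, edges,
                           cached_gc(as.matrix(edges[, c("a", "b")])),
                           list(cutoff = cutoff,
                                persistence = persistence))
    opt <- optimal_path(net, source, sink)
    ps <- if (opt$connected) suboptimal_paths(net, source, sink, count)
          else NULL
    list(net = net, ps = ps, edges = edges)
  }
  ref <- run_point(reference[1], reference[2])
  if (is.null(ref$ps))
    stop("source and sink are disconnected at the reference parameters")
  ref_edges <- .edge_keys(as.matrix(ref$edges[, c("a", "b")]))
  ref_res <- unique(unlist(ref$ps$paths))
  ref_conn <- .path_connections(ref$ps$paths)

  grid <- expand.grid(cutoff = cutoffs, persistence = persistences)
  occ <- matrix(NA_real_, length(nodes), nrow(grid))
  rows <- vector("list", nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    co <- grid$cutoff[gidx]; pe <- grid$persistence[gidx]
    pt <- run_point(co, pe)
    if (is.null(pt$ps)) {
      rows[[gidx]] <- data.frame(cutoff = co, persistence = pe,
                                 jaccard_edges = NA_real_,
                                 jaccard_residues = NA_real_,
                                 jaccard_connections = NA_real_,
                                 connected = FALSE)
      next
    }
    ed <- .edge_keys(as.matrix(pt$edges[, c("a", "b")]))
    res <- unique(unlist(pt$ps$paths))
    conn <- .path_connections(pt$ps$paths)
    occ[, gidx] <- pt$ps$occurrence
    rows[[gidx]] <- data.frame(cutoff = co, persistence = pe,
                               jaccard_edges = jaccard(ref_edges, ed),
                               jaccard_residues = jaccard(ref_res, res),
                               jaccard_connections = jaccard(ref_conn,
                                                             conn),
                               connected = TRUE)
  }
  labels <- vapply(nodes, `[[`, character(1), "label")
  rownames(occ) <- labels
  list(grid = do.call(rbind, rows), occurrence = occ,
       reference = reference)
}
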