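# Dynamic network construction, generalized correlation, path tracing,
# communities, betweenness and sensitivity scans.

test_that("node assignment covers protein, ligand split and ion", {
  g <- make_planted_network_ensemble(n_frames = 100, seed = 30)
  nodes <- assign_nodes(g$topology, select_atoms(g$topology, "all"))
  expect_length(nodes, 30)

  # chain + ATP-like ligand + ion -> 30 + 2 + 1 nodes
  atp_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8",
                 "N9", "C1'", "O4'", "PA", "PB", "PG", "O1A", "O1B",
                 "O1G")
  nm <- c(g$topology$atoms$name, atp_names, "MG")
  rid <- c(g$topology$atoms$resid, rep(31L, length(atp_names)), 32L)
  rn <- c(g$topology$atoms$resname, rep("ATP", length(atp_names)), "MG")
  top2 <- topology(name = nm, resid = rid, resname = rn)
  prot <- select_atoms(top2, "resid 1-30")
  lig <- list(atp = select_atoms(top2, "resname ATP"),
              mg = select_atoms(top2, "resname MG"))
  nodes2 <- assign_nodes(top2, prot, lig)
  expect_length(nodes2, 33)
  # ring heavies to the N1 node, the rest to the gamma-phosphate node
  labels <- vapply(nodes2, `[[`, character(1), "label")
  ring_node <- nodes2[[which(labels == "atp:ring")]]
  pg_node <- nodes2[[which(labels == "atp:pgamma")]]
  expect_setequal(top2$atoms$name[ring_node$atoms],
                  c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7",
                    "C8", "N9"))
  expect_true("PG" %in% top2$atoms$name[pg_node$atoms])
  # partition: every heavy atom in exactly one node
  all_atoms <- unlist(lapply(nodes2, `[[`, "atoms"))
  expect_equal(sort(all_atoms), which(top2$atoms$heavy))
})

test_that("edge persistence thresholds bracket correctly", {
  # two beads 0.38 nm apart in 70% of frames, far otherwise
  near <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  far <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  frames <- c(replicate(7, near, simplify = FALSE),
              replicate(3, far, simplify = FALSE))
  ens <- bead_ensemble(frames)
  nodes <- assign_nodes(ens$topology, select_atoms(ens$topology, "all"))
  expect_equal(nrow(build_edges(ens, nodes, 0.45, 0.75)), 0)
  expect_equal(nrow(build_edges(ens, nodes, 0.45, 0.65)), 1)
  # always in contact: edge at the reference parameters
  ens2 <- bead_ensemble(replicate(10, near, simplify = FALSE))
  nodes2 <- assign_nodes(ens2$topology,
                         select_atoms(ens2$topology, "all"))
  expect_equal(nrow(build_edges(ens2, nodes2, 0.45, 0.75)), 1)
})

test_that("edge sets equal a brute-force distance recount", {
  g <- make_planted_network_ensemble(n_frames = 100, seed = 31,
                                     sigma = 0.08)
  nodes <- assign_nodes(g$topology, select_atoms(g$topology, "all"))
  edges <- build_edges(g$ensemble, nodes, 0.45, 0.75)
  got <- paste(edges$a, edges$b)
  want <- character(0)
  for (i in 1:29) for (j in (i + 1):30) {
    d <- sqrt(rowSums((g$ensemble$coords[, i, ] -
                         g$ensemble$coords[, j, ])^2))
    if (mean(d <= 0.45) >= 0.75) want <- c(want, paste(i, j))
  }
  expect_setequal(got, want)
})

test_that("GC matches the Gaussian closed form across rho", {
  set.seed(32)
  n <- 5000
  for (rho in c(0, 0.3, 0.5, 0.8, 0.95)) {
    x <- matrix(rnorm(n * 3), n, 3)
    y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * 3), n, 3)
    top <- topology(name = c("CA", "CA"), resid = 1:2,
                    resname = c("ALA", "ALA"))
    coords <- array(NA_real_, dim = c(n, 2, 3))
    coords[, 1, ] <- x
    coords[, 2, ] <- y + 1    # spatial offset is irrelevant to GC
    ens <- frame_ensemble(top, coords)
    nodes <- assign_nodes(top, select_atoms(top, "all"))
    gc_val <- generalized_correlation(ens, nodes, cbind(1, 2))
    # at independence the sqrt mapping inflates small positive MI noise;
    # the null bound is 0.1, correlated pairs are tight
    if (rho == 0) expect_lt(gc_val, 0.1)
    else expect_lt(abs(gc_val - rho), 0.05)
  }
})

test_that("degenerate GC inputs are caught", {
  top <- topology(name = c("CA", "CA"), resid = 1:2,
                  resname = c("ALA", "ALA"))
  set.seed(33)
  x <- matrix(rnorm(600 * 3, sd = 0.05), 600, 3)
  coords <- array(NA_real_, dim = c(600, 2, 3))
  coords[, 1, ] <- x
  coords[, 2, ] <- x       # duplicated series
  ens <- frame_ensemble(top, coords)
  nodes <- assign_nodes(top, select_atoms(top, "all"))
  gc_dup <- generalized_correlation(ens, nodes, cbind(1, 2))
  expect_gt(gc_dup, 0.9)   # estimator saturates near (not at) 1
  expect_lt(gc_dup, 1)
  # zero-variance node errors with its name
  coords[, 2, ] <- 0
  ens0 <- frame_ensemble(top, coords)
  expect_error(generalized_correlation(ens0, nodes, cbind(1, 2)),
               "zero variance")
})

test_that("Floyd-Warshall costs equal a Dijkstra oracle on random graphs", {
  for (s in 1:100) {
    edges <- random_weighted_graph(20, extra = 25, seed = 400 + s)
    net <- net_from_edgelist(edges, 20)
    fw <- floyd_warshall(allonet:::.net_dmat(net))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$a, to = edges$b), directed = FALSE,
      vertices = data.frame(name = 1:20))
    want <- igraph::distances(g, weights = edges$w,
                              algorithm = "dijkstra")
    want <- want[as.character(1:20), as.character(1:20)]
    expect_lt(max(abs(fw$dist - want)), 1e-9)
  }
})

test_that("optimal path reconstruction matches its cost", {
  edges <- random_weighted_graph(12, extra = 10, seed = 77)
  net <- net_from_edgelist(edges, 12)
  opt <- optimal_path(net, 1, 12)
  expect_true(opt$connected)
  dmat <- allonet:::.net_dmat(net)
  steps <- cbind(opt$path[-length(opt$path)], opt$path[-1])
  expect_equal(sum(dmat[steps]), opt$cost, tolerance = 1e-12)
  expect_false(anyDuplicated(opt$path) > 0)
})

test_that("disconnected source/sink yields an explicit no-path result", {
  edges <- data.frame(a = c(1, 3), b = c(2, 4), w = c(1, 1))
  net <- net_from_edgelist(edges, 4)
  opt <- optimal_path(net, 1, 4)
  expect_false(opt$connected)
  expect_null(opt$path)
  expect_equal(opt$cost, Inf)
})

test_that("suboptimal paths equal exhaustive enumeration on small graphs", {
  for (s in 1:5) {
    edges <- random_weighted_graph(8, extra = 8, seed = 500 + s)
    net <- net_from_edgelist(edges, 8)
    ps <- suboptimal_paths(net, 1, 8, count = 1000)
    oracle <- oracle_all_simple_paths(edges, 8, 1, 8)
    expect_equal(length(ps$paths), length(oracle$paths))
    expect_equal(ps$costs, oracle$costs, tolerance = 1e-9)
    expect_true(ps$exhausted)
    expect_true(all(diff(ps$costs) > -1e-12))
    for (p in ps$paths) expect_false(anyDuplicated(p) > 0)
  }
})

test_that("path sets exhaust gracefully and count occurrences", {
  # diamond: exactly 3 simple paths from 1 to 4
  edges <- data.frame(a = c(1, 1, 2, 3, 1), b = c(2, 3, 4, 4, 4),
                      w = c(1, 2, 1, 2, 10))
  net <- net_from_edgelist(edges, 4)
  ps <- suboptimal_paths(net, 1, 4, count = 20)
  expect_length(ps$paths, 3)
  expect_true(ps$exhausted)
  expect_equal(unname(ps$occurrence[c("1", "4")]), c(1, 1))
  expect_equal(unname(ps$occurrence["2"]), 1 / 3)
  # optimal cost is the minimum over the set
  expect_equal(ps$costs[1], 2)
})

test_that("planted allosteric path is recovered from the ensemble", {
  g <- make_planted_network_ensemble(n_frames = 2000, seed = 34)
  nodes <- assign_nodes(g$topology, select_atoms(g$topology, "all"))
  net <- network_from_ensemble(g$ensemble, nodes)
  chain <- g$truth$planted_path
  opt <- optimal_path(net, chain[1], chain[length(chain)])
  expect_equal(opt$path, chain)
  ps <- suboptimal_paths(net, chain[1], chain[length(chain)], 20)
  planted_occ <- min(ps$occurrence[as.character(chain)])
  background_occ <- max(ps$occurrence[setdiff(names(ps$occurrence),
                                              as.character(chain))])
  expect_gt(planted_occ, background_occ)
})

test_that("two weakly joined cliques give exactly two communities", {
  # complete 10-cliques with strong weights, one weak bridging edge
  edges <- NULL
  for (blk in 0:1) for (i in 1:9) for (j in (i + 1):10)
    edges <- rbind(edges, data.frame(a = blk * 10 + i, b = blk * 10 + j,
                                     w = 0.3))
  edges <- rbind(edges, data.frame(a = 10, b = 11, w = 5))
  net <- net_from_edgelist(edges, 20)
  cm <- detect_communities(net, seed = 0)
  expect_length(cm$sizes, 2)
  expect_length(unique(cm$membership[1:10]), 1)
  expect_length(unique(cm$membership[11:20]), 1)
  expect_false(cm$membership[1] == cm$membership[20])
})

test_that("planted partitions are recovered across seeds", {
  skip_if_not_installed("mclust")
  for (s in 1:3) {
    pp <- make_planted_partition_ensemble(seed = s, n_frames = 1500)
    nodes <- assign_nodes(pp$topology, select_atoms(pp$topology, "all"))
    net <- network_from_ensemble(pp$ensemble, nodes)
    cm <- detect_communities(net, seed = 0)
    ari <- mclust::adjustedRandIndex(cm$membership,
                                     pp$truth$planted_partition)
    expect_gte(ari, 0.9)
  }
})

test_that("communities below 1% of nodes are discarded", {
  # 200-node ring plus a detached 1-node satellite (its own community)
  n <- 201
  edges <- data.frame(a = 1:199, b = 2:200, w = 0.3)
  edges <- rbind(edges, data.frame(a = 200, b = 1, w = 0.3))
  net <- net_from_edgelist(edges, n)
  cm <- detect_communities(net, seed = 0)
  expect_true(201 %in% cm$discarded)
  expect_true(is.na(cm$membership[201]))
  # every retained community respects the 1% floor
  expect_true(all(table(cm$membership) >= 0.01 * n))
})

test_that("node betweenness fractions match path-graph enumeration", {
  path3 <- net_from_edgelist(data.frame(a = 1:2, b = 2:3, w = 1), 3)
  cm3 <- detect_communities(path3, seed = 0, discard_below = 0)
  bc3 <- community_betweenness(path3, cm3)
  expect_equal(unname(bc3$node_betweenness[2]), 1)

  path5 <- net_from_edgelist(data.frame(a = 1:4, b = 2:5, w = 1), 5)
  cm5 <- detect_communities(path5, seed = 0, discard_below = 0)
  bc5 <- community_betweenness(path5, cm5)
  expect_equal(unname(bc5$node_betweenness[3]), 4 / 6)

  # complete graph: no shortest path passes through interior nodes
  edges <- NULL
  for (i in 1:4) for (j in (i + 1):5)
    edges <- rbind(edges, data.frame(a = i, b = j, w = 1))
  complete <- net_from_edgelist(edges, 5)
  cmc <- detect_communities(complete, seed = 0, discard_below = 0)
  bcc <- community_betweenness(complete, cmc)
  expect_true(all(bcc$node_betweenness == 0))
})

test_that("jaccard handles standard and degenerate set pairs", {
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(1:3, 1:3), 1)
})

test_that("sensitivity scan is exact at the reference grid point", {
  g <- make_planted_network_ensemble(n_frames = 1000, seed = 35)
  nodes <- assign_nodes(g$topology, select_atoms(g$topology, "all"))
  chain <- g$truth$planted_path
  sc <- sensitivity_scan(g$ensemble, nodes, chain[1],
                         chain[length(chain)],
                         cutoffs = 0.45, persistences = c(0.65, 0.75))
  ref_row <- sc$grid[abs(sc$grid$cutoff - 0.45) < 1e-9 &
                       abs(sc$grid$persistence - 0.75) < 1e-9, ]
  expect_equal(ref_row$jaccard_edges, 1)
  expect_equal(ref_row$jaccard_residues, 1)
  expect_equal(ref_row$jaccard_connections, 1)
  expect_error(
    sensitivity_scan(g$ensemble, nodes, chain[1], chain[6],
                     cutoffs = 0.42, persistences = 0.65),
    "reference parameters")
})
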