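edges_of <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(node_a = m[, 1], node_b = m[, 2], combined_score = 1)
}

test_that("typed networks enforce simplicity and valid scores", {
  nodes <- data.frame(node_id = c("a", "b", "c"), role = "putative_target")
  expect_error(typed_network(nodes, edges_of("a", "z")), "absent")
  e <- rbind(edges_of("a", "b", "b", "a", "a", "a"), NULL)
  e$combined_score <- c(0.4, 0.9, 0.5)
  expect_warning(expect_warning(net <- typed_network(nodes, e), "self-loop"),
                 "duplicate")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$combined_score, 0.9)  # max kept on collapse
  e2 <- edges_of("a", "b")
  e2$combined_score <- 1.2
  expect_error(typed_network(nodes, e2), "\\[0, 1\\]")
})

test_that("median score filtering is strict and keeps at most half", {
  e <- edges_of("a", "b", "b", "c", "c", "d", "d", "a")
  e$combined_score <- c(0.2, 0.4, 0.6, 0.8)
  out <- filter_edges_by_median_score(e)
  expect_equal(sort(out$combined_score), c(0.6, 0.8))
  expect_equal(attr(out, "retained_fraction"), 0.5)
  e$combined_score <- rep(0.7, 4)
  expect_warning(none <- filter_edges_by_median_score(e), "all edges dropped")
  expect_equal(nrow(none), 0)
  expect_error(filter_edges_by_median_score(e[0, ]), "empty")
  set.seed(1)
  for (i in 1:20) {
    e$combined_score <- runif(4)
    expect_lte(attr(filter_edges_by_median_score(e), "retained_fraction"), 0.5)
  }
})

test_that("centralities match hand-worked small graphs", {
  ## triangle: all degrees 2
  topo <- node_topology(edges_of("a", "b", "b", "c", "c", "a"))
  expect_equal(topo$degree, c(2L, 2L, 2L))
  ## star with 5 leaves + an isolated node
  star <- edges_of("hub", "l1", "hub", "l2", "hub", "l3", "hub", "l4", "hub", "l5")
  topo <- node_topology(star, nodes = c("hub", paste0("l", 1:5), "iso"))
  expect_equal(topo[topo$node_id == "hub", ]$degree, 5L)
  expect_equal(topo[topo$node_id == "l1", ]$degree, 1L)
  expect_equal(topo[topo$node_id == "iso", ]$degree, 0L)
  expect_equal(topo[topo$node_id == "iso", ]$closeness, 0)
  ## path a-b-c: betweenness 1 at the middle, closeness 1 and 2/3
  topo <- node_topology(edges_of("a", "b", "b", "c"))
  expect_equal(topo$betweenness, c(0, 1, 0))
  expect_equal(topo$closeness, c(2 / 3, 1, 2 / 3))
  ## star with 4 leaves: center carries all C(4,2) pairs
  topo <- node_topology(edges_of("h", "a", "h", "b", "h", "c", "h", "d"))
  expect_equal(topo[topo$node_id == "h", ]$betweenness, 6)
  ## 4-cycle: two shortest paths per opposite pair, half a pair each
  topo <- node_topology(edges_of("a", "b", "b", "c", "c", "d", "d", "a"))
  expect_equal(topo$betweenness, rep(0.5, 4))
  ## complete graph: closeness 1 everywhere
  topo <- node_topology(edges_of("a", "b", "b", "c", "c", "a", "a", "d",
                                 "b", "d", "c", "d"))
  expect_equal(topo$closeness, rep(1, 4))
  ## two disjoint edges: component-wise closeness is 1
  topo <- node_topology(edges_of("a", "b", "c", "d"))
  expect_equal(topo$closeness, rep(1, 4))
})

test_that("centralities agree with the brute-force oracle on every 5-node graph", {
  n <- 5
  n_pairs <- n * (n - 1) / 2
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  mismatches <- 0
  for (code in 0:(2^n_pairs - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
    A <- matrix(0, n, n)
    A[pair_idx] <- bits
    A <- A + t(A)
    oracle <- bf_centralities(A)
    got <- pkg_centralities(A)
    ok <- isTRUE(all.equal(got$degree, unname(oracle$degree))) &&
      isTRUE(all.equal(got$betweenness, oracle$betweenness, tolerance = 1e-12)) &&
      isTRUE(all.equal(got$closeness, oracle$closeness, tolerance = 1e-12))
    if (!ok) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("centralities agree with the oracle on random graphs incl. disconnected ones", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    A <- random_adj(n, runif(1, 0.15, 0.8))
    oracle <- bf_centralities(A)
    got <- pkg_centralities(A)
    expect_equal(got$degree, unname(oracle$degree))
    expect_equal(got$betweenness, oracle$betweenness, tolerance = 1e-12)
    expect_equal(got$closeness, oracle$closeness, tolerance = 1e-12)
  }
})

test_that("the triple-median hub screen matches the independent filter", {
  ## all nodes identical: nothing strictly exceeds the median
  cyc <- node_topology(edges_of("a", "b", "b", "c", "c", "d", "d", "a"))
  expect_length(select_hubs(cyc)$hubs, 0)
  ## a single dominating node is the unique hub
  star <- node_topology(edges_of("h", "a", "h", "b", "h", "c", "a", "b"))
  sel <- select_hubs(star)
  expect_identical(sel$hubs, "h")
  expect_true(all(sel$audit[sel$audit$hub == TRUE,
                            c("pass_degree", "pass_betweenness",
                              "pass_closeness")] == TRUE))
  ## synthetic preferential-attachment graphs vs the sort-median-compare oracle
  for (seed in 1:15) {
    cfg <- network_sim_config(n_targets = 60, n_disease_targets = 30,
                              n_overlap = 10, seed = seed)
    net <- gen_ppi_and_pathways(cfg)
    topo <- node_topology(net$edges, nodes = net$nodes$node_id)
    expect_identical(select_hubs(topo)$hubs, oracle_hubs(topo))
  }
})

test_that("hub selection is invariant under order-preserving relabeling and monotone in the cut", {
  cfg <- network_sim_config(n_targets = 50, n_disease_targets = 25,
                            n_overlap = 5, seed = 77)
  net <- gen_ppi_and_pathways(cfg)
  topo <- node_topology(net$edges, nodes = net$nodes$node_id)
  sel <- select_hubs(topo)
  ## order-preserving relabeling: prefix every id (keeps lexicographic order)
  relab <- data.table::copy(topo)
  relab[, node_id := paste0("x_", node_id)]
  expect_identical(select_hubs(relab)$hubs, paste0("x_", sel$hubs))
  ## replacing a median by any larger cut never adds hubs
  for (metric in c("degree", "betweenness", "closeness")) {
    cuts <- sel$cuts
    audit <- sel$audit
    bigger <- cuts[[metric]] + diff(range(topo[[metric]])) * 0.25
    manual <- audit$node_id[audit$degree > max(cuts[["degree"]],
                                               if (metric == "degree") bigger else -Inf) &
                            audit$betweenness > max(cuts[["betweenness"]],
                                               if (metric == "betweenness") bigger else -Inf) &
                            audit$closeness > max(cuts[["closeness"]],
                                               if (metric == "closeness") bigger else -Inf)]
    expect_true(all(manual %in% sel$hubs))
  }
})
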