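# Cost thresholding, efficiency metrics, null models, degree fits

test_that("cost thresholding keeps exactly the strongest pairs", {
  m <- matrix(0, 5, 5)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  g <- threshold_at_cost(m, 1)
  expect_equal(g$k, 10)
  g4 <- threshold_at_cost(m, 0.4)
  expect_equal(g4$k, 4)
  kept <- m[fcnet:::graph_edges(g4)]
  expect_setequal(kept, sort(vals, decreasing = TRUE)[1:4])
  # K rounds half away from zero: 0.45 * 10 = 4.5 -> 5 edges
  expect_equal(threshold_at_cost(m, 0.45)$k, 5)
})

test_that("thresholded edge sets are nested across increasing costs", {
  set.seed(14)
  m <- abs(stats::rnorm(20 * 20))
  m <- matrix(m, 20, 20)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- NA
  prev <- NULL
  for (cost in c(0.1, 0.2, 0.35, 0.5, 0.8)) {
    g <- threshold_at_cost(m, cost)
    edges <- apply(fcnet:::graph_edges(g), 1, paste, collapse = "-")
    if (!is.null(prev)) expect_true(all(prev %in% edges))
    prev <- edges
  }
})

test_that("undefined entries in the retained range are an error", {
  m <- matrix(0.5, 4, 4)
  diag(m) <- NA
  m[1, 2] <- m[2, 1] <- NA
  expect_error(threshold_at_cost(m, 1), "undefined")
})

test_that("efficiency metrics match closed forms on canonical graphs", {
  path3 <- fcnet:::graph_from_edges(rbind(c(1, 2), c(2, 3)), 3)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))

  complete5 <- binary_graph(matrix(1, 5, 5) - diag(5))
  expect_equal(global_efficiency(complete5), 1)
  expect_equal(local_efficiency(complete5), 1)

  empty4 <- binary_graph(matrix(0, 4, 4))
  expect_equal(global_efficiency(empty4), 0)
  expect_equal(unname(nodal_efficiency(empty4)), rep(0, 4))

  triangle <- binary_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(local_efficiency(triangle), 1)

  # trees have no neighbor-neighbor links: local efficiency 0
  star6 <- fcnet:::graph_from_edges(cbind(1, 2:6), 6)
  expect_equal(local_efficiency(star6), 0)
  # star center reaches everyone directly; leaves take two hops
  star4 <- fcnet:::graph_from_edges(cbind(1, 2:4), 4)
  ne <- unname(nodal_efficiency(star4))
  expect_equal(ne[1], 1)
  expect_equal(ne[2], 2 / 3)
  expect_equal(unname(betweenness_centrality(star4)), c(1, 0, 0, 0))

  # isolated node contributes zero nodal efficiency
  iso <- fcnet:::graph_from_edges(rbind(c(1, 2)), 3)
  expect_equal(unname(nodal_efficiency(iso))[3], 0)
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, p = runif(1, 0.2, 0.8))
    expect_graph_metrics_match(adj)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(44)
  for (rep in 1:20) {
    adj <- random_adjacency(8, 0.3)
    free <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(free)) next
    pick <- free[sample(nrow(free), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- TRUE
    expect_gte(global_efficiency(binary_graph(adj2)),
               global_efficiency(binary_graph(adj)))
  }
})

test_that("the random null preserves the degree sequence exactly", {
  set.seed(3)
  g <- binary_graph(random_adjacency(25, 0.25))
  r1 <- matched_random_graph(g, seed = 5)
  expect_equal(node_degree(r1), node_degree(g))
  expect_identical(matched_random_graph(g, seed = 5)$adj, r1$adj)
  expect_false(identical(r1$adj, g$adj))
})

test_that("the regular null matches node and edge counts with uniform degrees", {
  g <- binary_graph(random_adjacency(10, 0.5))
  reg <- matched_regular_graph(g)
  expect_equal(reg$n, g$n)
  expect_equal(reg$k, g$k)
  ring10 <- fcnet:::ring_lattice_nk(10, 10)
  expect_true(all(node_degree(ring10) == 2))
})

test_that("rewiring a lattice raises global and lowers local efficiency", {
  lat <- fcnet:::ring_lattice_nk(60, 180)
  rnd <- matched_random_graph(lat, seed = 8)
  expect_gt(global_efficiency(rnd), global_efficiency(lat))
  expect_lt(local_efficiency(rnd), local_efficiency(lat))
})

test_that("a single passing cost yields a single-point regime", {
  g <- generate_benchmark_graph("watts_strogatz", 100, 6, 0.1, seed = 5)
  conn <- graph_connectivity(g, seed = 11)
  cost0 <- graph_cost(g)
  sw <- small_world_regime(conn, grid = cost0, n_null = 10, seed = 2)
  expect_equal(sw$regime, c(lo = cost0, hi = cost0))
  expect_true(sw$table$small_world[1])
})

test_that("graphs round-trip through edge-list TSVs", {
  set.seed(71)
  g <- binary_graph(random_adjacency(12, 0.3), nodes = paste0("N", 1:12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list_tsv(g, path)
  back <- read_edge_list_tsv(path, g$nodes)
  expect_identical(back$adj, g$adj)
  expect_error(read_edge_list_tsv(path, g$nodes[1:5]), "unknown node")
})

test_that("truncated power-law fitting flags degenerate input and recovers the exponential family", {
  flat <- fit_truncated_power_law(rep(4, 30))
  expect_false(flat$converged)
  expect_true(is.na(flat$alpha))
  k <- sample_truncated_power_law(4000, alpha = 1.0, kc = 5, seed = 19)
  f <- fit_truncated_power_law(k, k_max = 200)
  expect_true(f$converged)
  expect_lt(abs(f$alpha - 1.0), 0.15)
  expect_error(fit_truncated_power_law(c(1, 2, 3)), "10")
})

test_that("the CCDF fit variant agrees roughly with maximum likelihood", {
  k <- sample_truncated_power_law(4000, alpha = 1.6, kc = 5, seed = 23)
  ml <- fit_truncated_power_law(k, k_max = 200)
  ls <- fit_truncated_power_law(k, k_max = 200, method = "ccdf")
  expect_true(ls$converged)
  expect_lt(abs(ml$alpha - ls$alpha), 0.3)
})
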