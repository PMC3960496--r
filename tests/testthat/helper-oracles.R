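# Independent brute-force oracles for graph metrics and components.
# These deliberately use different algorithms from the package: shortest
# paths and path counts come from adjacency-matrix powers (a walk of
# minimal length is necessarily a shortest path, and the number of such
# walks equals the number of shortest paths), components from union-find.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  a <- matrix(as.numeric(adj), n, n)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  p <- diag(n)
  for (l in seq_len(n - 1)) {
    p <- p %*% a
    newly <- p > 0 & !is.finite(d)
    if (!any(newly)) break
    d[newly] <- l
  }
  d
}

# number of shortest paths between every pair: (A^d_st)[s,t]
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  a <- matrix(as.numeric(adj), n, n)
  pow <- list(diag(n))
  maxd <- max(d[is.finite(d)])
  for (l in seq_len(max(maxd, 1))) pow[[l + 1]] <- pow[[l]] %*% a
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(d[s, t])) sig[s, t] <- pow[[d[s, t] + 1]][s, t]
  }
  sig
}

oracle_eglob <- function(adj) {
  n <- nrow(adj)
  inv <- 1 / oracle_distances(adj)
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_enodal <- function(adj) {
  n <- nrow(adj)
  inv <- 1 / oracle_distances(adj)
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

oracle_bc <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sig <- oracle_path_counts(adj, d)
  bc <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == i || t == i || !is.finite(d[s, t])) next
      if (is.finite(d[s, i]) && is.finite(d[i, t]) &&
          d[s, i] + d[i, t] == d[s, t])
        acc <- acc + sig[s, i] * sig[i, t] / sig[s, t]
    }
    bc[i] <- acc / ((n - 1) * (n - 2) / 2)
  }
  bc
}

# union-find connected components over an edge list
oracle_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(NROW(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# partition an edge list into components; returns sorted edge-count extents
oracle_component_extents <- function(edges, n) {
  if (!NROW(edges)) return(integer(0))
  memb <- oracle_components(edges, n)
  sort(as.integer(table(memb[edges[, 1]])), decreasing = TRUE)
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  up <- upper.tri(adj)
  adj[up] <- stats::runif(sum(up)) < p
  adj <- adj | t(adj)
  adj
}

# enumerate every labeled graph on n nodes (n small!)
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  up <- which(upper.tri(matrix(0, n, n)))
  lapply(0:(2^m - 1), function(code) {
    bits <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    adj <- matrix(FALSE, n, n)
    adj[up] <- bits
    adj | t(adj)
  })
}

expect_graph_metrics_match <- function(adj, tol = 1e-10) {
  g <- binary_graph(adj)
  testthat::expect_equal(global_efficiency(g), oracle_eglob(adj),
                         tolerance = tol)
  testthat::expect_equal(unname(nodal_efficiency(g)), oracle_enodal(adj),
                         tolerance = tol)
  testthat::expect_equal(local_efficiency(g), oracle_eloc(adj),
                         tolerance = tol)
  testthat::expect_equal(unname(node_degree(g)), as.integer(rowSums(adj)))
  if (nrow(adj) >= 3)
    testthat::expect_equal(unname(betweenness_centrality(g)), oracle_bc(adj),
                           tolerance = tol)
}
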