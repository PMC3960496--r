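# Binary graph construction and small-world topology metrics.
#
# Connectivity matrices are binarized by network cost: the cost of a graph
# with N nodes and K edges is K / (N(N-1)/2), and thresholding at a target
# cost keeps the K strongest connections.  All topology metrics operate on
# the resulting undirected, unweighted graph.

#' Construct a binary graph
#'
#' @param adj logical or 0/1 symmetric adjacency matrix; the diagonal is
#'   ignored.
#' @param nodes optional character node ids (defaults to rownames or V1..VN).
#' @return an object of class `fc_graph` with elements `adj` (logical
#'   matrix), `nodes`, `n` and `k` (edge count).
#' @export
binary_graph <- function(adj, nodes = NULL) {
  adj <- as.matrix(adj) != 0
  n <- nrow(adj)
  if (ncol(adj) != n) stopf("adjacency matrix must be square")
  if (!isTRUE(all(adj == t(adj)))) stopf("adjacency matrix must be symmetric")
  diag(adj) <- FALSE
  nodes <- nodes %||% rownames(adj) %||% paste0("V", seq_len(n))
  dimnames(adj) <- list(nodes, nodes)
  structure(list(adj = adj, nodes = nodes, n = n, k = sum(adj) / 2),
            class = "fc_graph")
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("<fc_graph> %d nodes, %d edges (cost %.3f)\n",
              x$n, x$k, graph_cost(x)))
  invisible(x)
}

#' Cost of a binary graph
#'
#' The fraction of present edges among all N(N-1)/2 possible node pairs.
#' @param g an `fc_graph`.
#' @return numeric scalar in \[0, 1\].
#' @export
graph_cost <- function(g) g$k / (g$n * (g$n - 1) / 2)

#' Edge list of a binary graph
#' @param g an `fc_graph`.
#' @return two-column integer matrix of node indices, i < j.
#' @export
graph_edges <- function(g) {
  idx <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Read / write a binary graph as an edge-list TSV
#'
#' Two columns `from`, `to` holding node ids; isolated nodes are implied
#' by the `nodes` argument on read.
#'
#' @param g an `fc_graph`.
#' @param path file path.
#' @export
write_edge_list_tsv <- function(g, path) {
  e <- graph_edges(g)
  utils::write.table(data.frame(from = g$nodes[e[, 1]],
                                to = g$nodes[e[, 2]]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list_tsv
#' @param nodes full node id vector (edge lists omit isolated nodes).
#' @export
read_edge_list_tsv <- function(path, nodes) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  bad <- setdiff(c(df$from, df$to), nodes)
  if (length(bad)) stopf("unknown node id(s) in %s: %s", path,
                         paste(unique(bad), collapse = ", "))
  graph_from_edges(cbind(match(df$from, nodes), match(df$to, nodes)),
                   length(nodes), nodes)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
}

graph_from_edges <- function(edges, n, nodes = NULL) {
  adj <- matrix(FALSE, n, n)
  if (NROW(edges)) {
    adj[cbind(edges[, 1], edges[, 2])] <- TRUE
    adj[cbind(edges[, 2], edges[, 1])] <- TRUE
  }
  binary_graph(adj, nodes)
}

#' Threshold a connectivity matrix at a network cost
#'
#' Keeps the `K = round(cost * N(N-1)/2)` strongest connections (rounding
#' half away from zero) as the edges of an undirected binary graph.  Ties in
#' connection strength are broken by lexicographic (i, j) node order, which
#' makes the edge sets nested across increasing costs.
#'
#' @param conn symmetric connectivity matrix (absolute correlations) or
#'   `fc_connectivity`.
#' @param cost target cost in (0, 1\].
#' @return an `fc_graph`.
#' @export
threshold_at_cost <- function(conn, cost) {
  m <- unclass_conn(conn)
  stopifnot(cost > 0, cost <= 1)
  n <- nrow(m)
  pairs <- upper_pairs(n)
  vals <- m[pairs]
  k <- round_half_away(cost * nrow(pairs))
  # strongest first; ties by (i, j) order (order() is stable)
  ord <- order(-vals)
  top <- ord[seq_len(k)]
  if (anyNA(vals[top])) {
    bad <- pairs[top[is.na(vals[top])], , drop = FALSE]
    stopf("undefined connectivity entries in the top-%d edges: %s", k,
          paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  }
  graph_from_edges(pairs[top, , drop = FALSE], n,
                   nodes = rownames(m) %||% NULL)
}

unclass_conn <- function(conn) {
  m <- if (inherits(conn, "fc_connectivity")) conn$matrix else as.matrix(conn)
  if (nrow(m) != ncol(m)) stopf("connectivity matrix must be square")
  m
}

# all-pairs shortest-path lengths by simultaneous BFS from every node:
# expand the reachable set one step per iteration with a boolean matrix
# product.  O(diameter) dense products, far faster in R than per-node BFS.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  a <- matrix(as.numeric(adj), n, n)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  curr <- adj
  step <- 1
  while (TRUE) {
    new <- curr & !reach
    if (!any(new)) break
    d[new] <- step
    reach <- reach | new
    curr <- (matrix(as.numeric(reach), n, n) %*% a) > 0
    step <- step + 1
  }
  d
}

# inverse shortest-path-length matrix; disconnected pairs contribute 0
inverse_distances <- function(g) {
  inv <- 1 / bfs_distances(g$adj)
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  inv
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' \eqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/l_{ij}}, with
#' \eqn{1/l_{ij} = 0} for disconnected pairs.
#'
#' @param g an `fc_graph` with at least 2 nodes.
#' @return numeric scalar in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  stopifnot(g$n >= 2)
  sum(inverse_distances(g)) / (g$n * (g$n - 1))
}

#' Nodal efficiency
#'
#' Per node i, the mean inverse distance to every other node:
#' \eqn{E_{nodal}(i) = \frac{1}{N-1} \sum_{j \ne i} 1/l_{ij}}.
#'
#' @param g an `fc_graph` with at least 2 nodes.
#' @return named numeric vector, one value in \[0, 1\] per node.
#' @export
nodal_efficiency <- function(g) {
  stopifnot(g$n >= 2)
  e <- rowSums(inverse_distances(g)) / (g$n - 1)
  names(e) <- g$nodes
  e
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's immediate neighbors (the node itself excluded); nodes with fewer
#' than two neighbors contribute 0.
#'
#' @param g an `fc_graph` with at least 2 nodes.
#' @return numeric scalar in \[0, 1\].
#' @export
local_efficiency <- function(g) {
  stopifnot(g$n >= 2)
  per_node <- vapply(seq_len(g$n), function(i) {
    nb <- which(g$adj[i, ])
    m <- length(nb)
    if (m < 2) return(0)
    inv <- 1 / bfs_distances(g$adj[nb, nb, drop = FALSE])
    inv[!is.finite(inv)] <- 0
    sum(inv) / (m * (m - 1))
  }, numeric(1))
  mean(per_node)
}

#' Node degree
#' @param g an `fc_graph`.
#' @return named integer vector of incident edge counts.
#' @export
node_degree <- function(g) {
  d <- as.integer(rowSums(g$adj))
  names(d) <- g$nodes
  d
}

#' Betweenness centrality
#'
#' The proportion of all shortest paths between pairs of other nodes that
#' pass through each node, normalized by the (N-1)(N-2)/2 pairs so values
#' lie in \[0, 1\]; endpoints are excluded.
#'
#' @param g an `fc_graph` with at least 3 nodes.
#' @return named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(g) {
  stopifnot(g$n >= 3)
  b <- igraph::betweenness(as_igraph(g), directed = FALSE, normalized = TRUE)
  b <- as.numeric(b)
  names(b) <- g$nodes
  b
}

#' Degree-matched random null graph
#'
#' Randomizes a graph by repeated double-edge swaps, preserving the exact
#' degree sequence; swaps that would create self-loops or duplicate edges
#' are skipped.
#'
#' @param g an `fc_graph` with at least 2 edges.
#' @param n_swap_attempts number of swap attempts (default 10 per edge).
#' @param seed integer RNG seed.
#' @return an `fc_graph` with the same degree sequence as `g`.
#' @export
matched_random_graph <- function(g, n_swap_attempts = 10 * g$k, seed = NULL) {
  stopifnot(g$k >= 2)
  ig <- as_igraph(g)
  rg <- with_seed(seed,
    igraph::rewire(ig, igraph::keeping_degseq(niter = n_swap_attempts)))
  binary_graph(as.matrix(igraph::as_adjacency_matrix(rg)), nodes = g$nodes)
}

#' Node- and edge-matched regular null graph
#'
#' Deterministic ring lattice with the same node and edge counts as the
#' input: every node is linked to its `floor(K/N)` nearest neighbors on
#' each side of a ring, and the remaining edges are assigned to
#' next-nearest neighbors starting from the first node, keeping the degree
#' sequence as uniform as the edge count permits.
#'
#' @param g an `fc_graph`.
#' @return an `fc_graph` with identical `n` and `k`.
#' @export
matched_regular_graph <- function(g) {
  ring_lattice_nk(g$n, g$k, nodes = g$nodes)
}

# ring lattice on n nodes with exactly k edges
ring_lattice_nk <- function(n, k, nodes = NULL) {
  max_k <- n * (n - 1) / 2
  if (k > max_k) stopf("cannot place %d edges on %d nodes", k, n)
  adj <- matrix(FALSE, n, n)
  placed <- 0
  dist <- 1
  while (placed < k) {
    ring_edges <- if (2 * dist < n) n else if (2 * dist == n) n / 2 else 0
    if (ring_edges == 0) stopf("ring lattice construction exhausted distances")
    take <- min(k - placed, ring_edges)
    for (i in seq_len(take)) {
      a <- i
      b <- ((i - 1 + dist) %% n) + 1
      adj[a, b] <- adj[b, a] <- TRUE
    }
    placed <- placed + take
    dist <- dist + 1
  }
  binary_graph(adj, nodes)
}

#' Small-world regime of a connectivity matrix
#'
#' Thresholds the connectivity matrix over a grid of costs and tests, at
#' each cost, the two small-world criteria against matched null models:
#' `E_glob(regular) < E_glob(G) < E_glob(random)` and
#' `E_loc(random) < E_loc(G) < E_loc(regular)`, where the random-null
#' efficiencies are ensemble means over `n_null` degree-preserving
#' rewirings and the regular null is the deterministic matched ring
#' lattice.  The regime is the longest contiguous run of costs passing both
#' criteria.
#'
#' @param conn connectivity matrix or `fc_connectivity`.
#' @param grid strictly increasing cost values in (0, 1).
#' @param n_null random-null ensemble size per cost (default 20).
#' @param seed integer RNG seed for the null ensembles.
#' @return an object of class `fc_small_world`: a list with `table` (one
#'   row per cost: efficiencies, null means, criterion flags) and `regime`
#'   (numeric `c(lo, hi)`, or NULL when no cost passes).
#' @export
small_world_regime <- function(conn, grid = seq(0.1, 0.5, by = 0.01),
                               n_null = 20, seed = NULL) {
  stopifnot(n_null >= 1, all(diff(grid) > 0), all(grid > 0), all(grid < 1))
  rows <- with_seed(seed, lapply(grid, function(cost) {
    g <- threshold_at_cost(conn, cost)
    eg <- global_efficiency(g)
    el <- local_efficiency(g)
    reg <- matched_regular_graph(g)
    eg_reg <- global_efficiency(reg)
    el_reg <- local_efficiency(reg)
    rand <- replicate(n_null, {
      r <- matched_random_graph(g)
      c(global_efficiency(r), local_efficiency(r))
    })
    eg_rand <- mean(rand[1, ])
    el_rand <- mean(rand[2, ])
    pass_glob <- eg_reg < eg && eg < eg_rand
    pass_loc <- el_rand < el && el < el_reg
    data.frame(cost = cost, e_glob = eg, e_loc = el,
               e_glob_regular = eg_reg, e_glob_random = eg_rand,
               e_loc_regular = el_reg, e_loc_random = el_rand,
               pass_glob = pass_glob, pass_loc = pass_loc,
               small_world = pass_glob && pass_loc)
  }))
  tab <- do.call(rbind, rows)
  regime <- longest_run_interval(grid, tab$small_world)
  structure(list(table = tab, regime = regime), class = "fc_small_world")
}

# longest contiguous TRUE run; ties resolved to the first run
longest_run_interval <- function(grid, pass) {
  if (!any(pass)) return(NULL)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  c(lo = grid[starts[best]], hi = grid[ends[best]])
}

#' @export
print.fc_small_world <- function(x, ...) {
  n_pass <- sum(x$table$small_world)
  cat(sprintf("<fc_small_world> %d/%d costs pass both criteria\n",
              n_pass, nrow(x$table)))
  if (is.null(x$regime)) cat("no small-world regime detected\n")
  else cat(sprintf("regime: cost in [%.2f, %.2f]\n",
                   x$regime[["lo"]], x$regime[["hi"]]))
  invisible(x)
}

#' Fit an exponentially truncated power law to a degree distribution
#'
#' Maximum-likelihood fit of the discrete distribution
#' \eqn{P(k) \propto k^{\alpha - 1} e^{-k / k_c}} over integer degrees
#' `k = 1 .. k_max` — a power law with exponent `alpha` truncated by an
#' exponential cutoff at degree `k_c`.  A least-squares fit to the
#' empirical complementary CDF is available as an alternative.
#'
#' @param degrees integer node degrees; zeros are dropped (support k >= 1)
#'   and at least 10 positive degrees are required.
#' @param k_max largest degree in the normalization support (default
#'   `max(degrees)`; use N - 1 for an N-node graph).
#' @param method `"ml"` (default) or `"ccdf"`.
#' @return an object of class `fc_degree_fit`: list with `alpha`, `kc`,
#'   `loss` (negative log-likelihood or residual sum of squares),
#'   `converged`, `method`, `n`.
#' @export
fit_truncated_power_law <- function(degrees, k_max = NULL,
                                    method = c("ml", "ccdf")) {
  method <- match.arg(method)
  k <- as.integer(degrees)
  k <- k[k >= 1]
  if (length(k) < 10) stopf("need at least 10 positive degrees")
  k_max <- as.integer(k_max %||% max(k))
  stopifnot(k_max >= max(k))
  if (length(unique(k)) < 2) {
    return(structure(list(alpha = NA_real_, kc = NA_real_, loss = NA_real_,
                          converged = FALSE, method = method, n = length(k)),
                     class = "fc_degree_fit"))
  }
  supp <- seq_len(k_max)
  obj <- if (method == "ml") {
    tab <- tabulate(k, nbins = k_max)
    function(par) {
      alpha <- par[1]; kc <- exp(par[2])
      logw <- (alpha - 1) * log(supp) - supp / kc
      lognorm <- log(sum(exp(logw - max(logw)))) + max(logw)
      -sum(tab * (logw - lognorm))
    }
  } else {
    ccdf_emp <- vapply(supp, function(x) mean(k >= x), numeric(1))
    function(par) {
      alpha <- par[1]; kc <- exp(par[2])
      logw <- (alpha - 1) * log(supp) - supp / kc
      w <- exp(logw - max(logw))
      ccdf_mod <- rev(cumsum(rev(w))) / sum(w)
      sum((log(ccdf_emp[ccdf_emp > 0]) - log(ccdf_mod[ccdf_emp > 0]))^2)
    }
  }
  fit <- tryCatch(
    stats::optim(c(1.5, log(mean(k))), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0 || !is.finite(fit$value)) {
    return(structure(list(alpha = NA_real_, kc = NA_real_, loss = NA_real_,
                          converged = FALSE, method = method, n = length(k)),
                     class = "fc_degree_fit"))
  }
  structure(list(alpha = fit$par[1], kc = exp(fit$par[2]), loss = fit$value,
                 converged = TRUE, method = method, n = length(k)),
            class = "fc_degree_fit")
}

#' @export
print.fc_degree_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fc_degree_fit> did not converge\n")
  } else {
    cat(sprintf("<fc_degree_fit> P(k) ~ k^(alpha-1) exp(-k/kc): alpha = %.3f, kc = %.3f (%s, n = %d)\n",
                x$alpha, x$kc, x$method, x$n))
  }
  invisible(x)
}

#' Sample degrees from a truncated power law
#'
#' Draws from the discrete distribution
#' \eqn{P(k) \propto k^{\alpha-1} e^{-k/k_c}} on `1..k_max`; the sampling
#' counterpart of [fit_truncated_power_law()].
#'
#' @param n number of draws.
#' @param alpha power-law exponent.
#' @param kc exponential cutoff degree.
#' @param k_max support upper bound.
#' @param seed integer RNG seed.
#' @return integer vector of length `n`.
#' @export
sample_truncated_power_law <- function(n, alpha, kc, k_max = 200, seed = NULL) {
  supp <- seq_len(k_max)
  logw <- (alpha - 1) * log(supp) - supp / kc
  p <- exp(logw - max(logw))
  with_seed(seed, sample(supp, n, replace = TRUE, prob = p / sum(p)))
}
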