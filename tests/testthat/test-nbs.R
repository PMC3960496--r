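# Network-based statistic: edge tests, components, permutation FWE

random_conn_list <- function(n_subj, n_nodes, seed, shift = 0) {
  set.seed(seed)
  lapply(seq_len(n_subj), function(s) {
    m <- matrix(runif(n_nodes^2, 0.2, 0.8) + shift, n_nodes, n_nodes)
    m <- (m + t(m)) / 2
    diag(m) <- NA
    m
  })
}

test_that("identical groups give t = 0 everywhere", {
  grp <- random_conn_list(4, 6, seed = 1)
  st <- edgewise_t(grp, grp)
  expect_true(all(abs(st$t[upper.tri(st$t)]) < 1e-12))
  expect_equal(st$df, 6)
})

test_that("edge t matches the textbook pooled formula", {
  # one edge with values {0.9, 0.8, 0.85} vs {0.4, 0.5, 0.45}
  mk <- function(v) {
    m <- matrix(c(NA, v, v, NA), 2, 2)
    m
  }
  a <- lapply(c(0.9, 0.8, 0.85), mk)
  b <- lapply(c(0.4, 0.5, 0.45), mk)
  st <- edgewise_t(a, b)
  ref <- t.test(c(0.9, 0.8, 0.85), c(0.4, 0.5, 0.45), var.equal = TRUE)
  expect_equal(st$t[1, 2], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(st$df, unname(ref$parameter))
})

test_that("swapping group labels negates every t", {
  a <- random_conn_list(5, 7, seed = 2)
  b <- random_conn_list(5, 7, seed = 3)
  expect_equal(edgewise_t(a, b)$t, -edgewise_t(b, a)$t)
})

test_that("zero pooled variance marks the edge undefined", {
  a <- lapply(1:3, function(i) matrix(c(NA, 0.5, 0.5, NA), 2, 2))
  st <- edgewise_t(a, a)
  expect_true(is.na(st$t[1, 2]))
})

test_that("suprathreshold components follow the constructed topology", {
  tm <- symmetric_t_matrix(8, list(c(1, 2, 4), c(2, 3, 4.5), c(5, 6, 4),
                                   c(7, 8, -4)))
  st <- edge_stats_from_matrix(tm)
  comps <- suprathreshold_components(st, 3.5, "a_gt_b")
  expect_length(comps, 2)
  expect_setequal(vapply(comps, `[[`, 0L, "extent"), c(2L, 1L))
  rev_comps <- suprathreshold_components(st, 3.5, "b_gt_a")
  expect_length(rev_comps, 1)
  expect_equal(rev_comps[[1]]$nodes, c(7L, 8L))
  none <- suprathreshold_components(st, 10, "a_gt_b")
  expect_length(none, 0)
})

test_that("components match a union-find oracle on random statistics", {
  set.seed(12)
  for (rep in 1:10) {
    n <- 30
    tm <- matrix(rnorm(n * n, sd = 2), n, n)
    tm <- (tm + t(tm)) / 2
    diag(tm) <- NA
    st <- edge_stats_from_matrix(tm)
    comps <- suprathreshold_components(st, 1.5, "a_gt_b")
    pairs <- which(upper.tri(tm) & tm > 1.5, arr.ind = TRUE)
    expect_setequal(vapply(comps, `[[`, 0L, "extent"),
                    oracle_component_extents(pairs, n))
  }
})

test_that("permutation p equals exhaustive enumeration on a 3 vs 3 toy", {
  a <- random_conn_list(3, 8, seed = 5, shift = 0.15)
  b <- random_conn_list(3, 8, seed = 6)
  res <- nbs_permutation(a, b, t_threshold = 2.5, exhaustive = TRUE)
  expect_equal(res$n_perm, choose(6, 3))

  # independent oracle: every split, t.test per edge, union-find extents
  mats <- c(a, b)
  n <- 8
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), ]
  evals <- sapply(mats, function(m) m[up])
  splits <- combn(6, 3, simplify = FALSE)
  max_ext <- sapply(splits, function(idx) {
    tv <- apply(evals, 1, function(v)
      tryCatch(t.test(v[idx], v[-idx], var.equal = TRUE)$statistic,
               error = function(e) 0))
    sup_a <- up[tv > 2.5, , drop = FALSE]
    sup_b <- up[-tv > 2.5, , drop = FALSE]
    c(a_gt_b = max(c(0L, oracle_component_extents(sup_a, n))),
      b_gt_a = max(c(0L, oracle_component_extents(sup_b, n))))
  })
  for (i in seq_len(nrow(res$components))) {
    dir <- res$components$direction[i]
    k <- res$components$extent[i]
    expect_equal(res$components$fwe_p[i], mean(max_ext[dir, ] >= k))
  }
})

test_that("FWE p is monotone non-increasing in extent within one result", {
  coh <- generate_cohort(small_spec(effect_size = 0.9, seed = 8))
  conns <- lapply(coh$timeseries, build_connectivity)
  ctrl <- coh$design$group == "control"
  res <- nbs_permutation(conns[ctrl], conns[!ctrl], t_threshold = 2.0,
                         n_perm = 200, seed = 4)
  for (dir in unique(res$components$direction)) {
    sub <- res$components[res$components$direction == dir, ]
    ord <- order(sub$extent)
    expect_true(all(diff(sub$fwe_p[ord]) <= 0))
  }
  # p is exactly the stated proportion of the stored null
  for (i in seq_len(nrow(res$components))) {
    dir <- res$components$direction[i]
    expect_equal(res$components$fwe_p[i],
                 mean(res$null_max_extent[, dir] >= res$components$extent[i]))
  }
})

test_that("results are reproducible by seed and tiny n_perm warns", {
  a <- random_conn_list(3, 6, seed = 9, shift = 0.2)
  b <- random_conn_list(3, 6, seed = 10)
  r1 <- nbs_permutation(a, b, t_threshold = 2, n_perm = 50, seed = 3)
  r2 <- nbs_permutation(a, b, t_threshold = 2, n_perm = 50, seed = 3)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  expect_identical(r1$components, r2$components)
  expect_warning(nbs_permutation(a, b, n_perm = 10, seed = 1), "resolve")
})
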