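# Network-based statistic (NBS): edge-wise two-sample t-tests,
# suprathreshold connected components, and permutation-based
# family-wise-error-corrected component p-values.
#
# The statistic of each permutation is the extent (edge count) of the
# largest connected component formed by edges whose t statistic exceeds
# the threshold; the FWE p of an observed component of extent k is the
# proportion of permutations whose largest component is at least k.

# stack the upper triangles of a list of connectivity matrices into a
# subjects x edges matrix (upper_pairs order)
stack_edges <- function(mats) {
  mats <- lapply(mats, unclass_conn)
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != n))
    stopf("connectivity matrices differ in size")
  do.call(rbind, lapply(mats, upper_values))
}

# pooled-variance two-sample t statistics for every column of e,
# comparing rows idx_a against the rest
col_t_stats <- function(e, idx_a) {
  na <- length(idx_a)
  nb <- nrow(e) - na
  a <- e[idx_a, , drop = FALSE]
  b <- e[-idx_a, , drop = FALSE]
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0] <- NA_real_  # zero pooled variance: undefined
  t
}

#' Edge-wise two-sample t statistics
#'
#' Pooled-variance Student t per node pair on the absolute correlation
#' values, comparing group A against group B (df = n_a + n_b - 2).
#'
#' @param group_a,group_b lists of connectivity matrices
#'   (`fc_connectivity` or plain symmetric matrices), one per subject;
#'   each group needs at least 2 subjects.
#' @return an object of class `fc_edge_stats`: list with `t` (symmetric
#'   matrix, NA where the pooled variance is zero), `df`, `nodes`,
#'   `n_a`, `n_b`.
#' @export
edgewise_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  e <- stack_edges(c(group_a, group_b))
  n <- nrow(unclass_conn(group_a[[1]]))
  tv <- col_t_stats(e, seq_along(group_a))
  tm <- matrix(NA_real_, n, n)
  p <- upper_pairs(n)
  tm[p] <- tv
  tm[p[, c(2, 1)]] <- tv
  nodes <- rownames(unclass_conn(group_a[[1]])) %||% paste0("V", seq_len(n))
  dimnames(tm) <- list(nodes, nodes)
  structure(list(t = tm, df = length(group_a) + length(group_b) - 2,
                 nodes = nodes, n_a = length(group_a),
                 n_b = length(group_b)), class = "fc_edge_stats")
}

# connected components (node sets + edge counts) of an edge index set;
# edges indexes rows of pairs (two-column matrix of node ids)
edge_components <- function(edge_idx, pairs, n) {
  if (!length(edge_idx)) return(list())
  el <- pairs[edge_idx, , drop = FALSE]
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(ig) < n)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  memb <- igraph::components(ig)$membership
  comp_of_edge <- memb[el[, 1]]
  lapply(sort(unique(comp_of_edge)), function(cid) {
    sel <- comp_of_edge == cid
    list(edges = el[sel, , drop = FALSE],
         nodes = sort(unique(as.vector(el[sel, , drop = FALSE]))),
         extent = sum(sel))
  })
}

#' Suprathreshold connected components
#'
#' Extracts the maximal connected components of the graph formed by edges
#' whose t statistic exceeds the threshold in the requested direction.
#'
#' @param stats an `fc_edge_stats`.
#' @param t_threshold positive threshold on the t statistic (default 3.5).
#' @param direction `"a_gt_b"` (t > threshold) or `"b_gt_a"`
#'   (-t > threshold).
#' @return list of components, each with `edges` (two-column node-index
#'   matrix), `nodes`, and `extent` (edge count); empty list when no edge
#'   is suprathreshold.
#' @export
suprathreshold_components <- function(stats, t_threshold = 3.5,
                                      direction = c("a_gt_b", "b_gt_a")) {
  direction <- match.arg(direction)
  stopifnot(inherits(stats, "fc_edge_stats"), t_threshold > 0)
  n <- length(stats$nodes)
  pairs <- upper_pairs(n)
  tv <- stats$t[pairs]
  keep <- if (direction == "a_gt_b") which(tv > t_threshold)
          else which(-tv > t_threshold)
  edge_components(keep, pairs, n)
}

max_extent <- function(tv, t_threshold, pairs, n) {
  # extent of the largest suprathreshold component in each direction
  vapply(list(which(tv > t_threshold), which(-tv > t_threshold)),
         function(keep) {
           if (!length(keep)) return(0L)
           comps <- edge_components(keep, pairs, n)
           max(vapply(comps, `[[`, 0L, "extent"))
         }, integer(1))
}

#' Network-based statistic with permutation FWE correction
#'
#' Runs the full NBS: (1) per-subject connectivity matrices in, (2)
#' edge-wise pooled-variance t-tests, (3) thresholding at `t_threshold`,
#' (4) connected-component extraction, (5) permutation of group labels to
#' build the null distribution of the largest component extent, (6) FWE
#' p per observed component as the proportion of permutations whose
#' largest component is at least as large.  Both contrast directions are
#' extracted and tested separately, each against the null of its own
#' direction.
#'
#' @inheritParams edgewise_t
#' @param t_threshold component-forming threshold (default 3.5).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @param alpha significance level for flagging components (default 0.05).
#' @param add_one if TRUE, use the (b + 1)/(m + 1) permutation p-value
#'   instead of the plain proportion b/m (default FALSE).
#' @param exhaustive if TRUE, enumerate every group-size-preserving
#'   relabeling instead of sampling (feasible for small cohorts only);
#'   `n_perm` and `seed` are then ignored.
#' @return an object of class `fc_nbs`: list with `components` (data.frame:
#'   direction, extent, n_nodes, fwe_p, significant), `component_detail`
#'   (list of component edge/node sets), `null_max_extent` (n_perm x 2
#'   matrix), `t_threshold`, `n_perm`, `seed`, `warnings`.
#' @export
nbs_permutation <- function(group_a, group_b, t_threshold = 3.5,
                            n_perm = 10000, seed = NULL, alpha = 0.05,
                            add_one = FALSE, exhaustive = FALSE) {
  stopifnot(n_perm >= 1, length(group_a) >= 2, length(group_b) >= 2)
  e <- stack_edges(c(group_a, group_b))
  n_tot <- nrow(e)
  na <- length(group_a)
  if (exhaustive) {
    splits <- utils::combn(n_tot, na, simplify = FALSE)
    n_perm <- length(splits)
  }
  warn <- character(0)
  if (n_perm < 20) {
    warn <- sprintf("n_perm = %d cannot resolve p < 0.05", n_perm)
    warning(warn)
  }
  n <- nrow(unclass_conn(group_a[[1]]))
  pairs <- upper_pairs(n)
  stats <- edgewise_t(group_a, group_b)
  obs <- list(a_gt_b = suprathreshold_components(stats, t_threshold, "a_gt_b"),
              b_gt_a = suprathreshold_components(stats, t_threshold, "b_gt_a"))
  null_max <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      idx <- if (exhaustive) splits[[p]] else sample.int(n_tot, na)
      max_extent(col_t_stats(e, idx), t_threshold, pairs, n)
    }, integer(2)))
  })
  colnames(null_max) <- c("a_gt_b", "b_gt_a")
  rows <- list()
  detail <- list()
  for (dir in c("a_gt_b", "b_gt_a")) {
    for (comp in obs[[dir]]) {
      b <- sum(null_max[, dir] >= comp$extent)
      pval <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
      rows[[length(rows) + 1]] <- data.frame(
        direction = dir, extent = comp$extent,
        n_nodes = length(comp$nodes), fwe_p = pval,
        significant = pval < alpha, stringsAsFactors = FALSE)
      detail[[length(detail) + 1]] <- c(comp, list(direction = dir))
    }
  }
  components <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(0), extent = integer(0),
               n_nodes = integer(0), fwe_p = numeric(0),
               significant = logical(0))
  structure(list(components = components, component_detail = detail,
                 null_max_extent = null_max, t_threshold = t_threshold,
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 nodes = stats$nodes, warnings = warn),
            class = "fc_nbs")
}

#' @export
print.fc_nbs <- function(x, ...) {
  cat(sprintf("<fc_nbs> t threshold %.2f, %d permutations\n",
              x$t_threshold, x$n_perm))
  if (!nrow(x$components)) {
    cat("no suprathreshold components\n")
  } else {
    print(x$components, row.names = FALSE)
  }
  invisible(x)
}

#' Write an NBS result to disk
#'
#' Emits a JSON component report, the permutation null distribution of
#' the maximal component extent as TSV, and one edge-list TSV per
#' significant component.
#'
#' @param res an `fc_nbs`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_nbs_result <- function(res, dir) {
  stopifnot(inherits(res, "fc_nbs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(t_threshold = res$t_threshold, n_perm = res$n_perm,
         alpha = res$alpha, seed = res$seed, warnings = res$warnings,
         components = res$components),
    file.path(dir, "nbs_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.table(res$null_max_extent,
                     file.path(dir, "nbs_null_max_extent.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- which(res$components$significant)
  for (i in sig) {
    comp <- res$component_detail[[i]]
    utils::write.table(
      data.frame(from = res$nodes[comp$edges[, 1]],
                 to = res$nodes[comp$edges[, 2]],
                 direction = comp$direction),
      file.path(dir, sprintf("nbs_component_%02d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
summary.fc_nbs <- function(object, ...) {
  sig <- object$components[object$components$significant, , drop = FALSE]
  cat(sprintf("NBS: %d component(s), %d significant at FWE p < %.2f\n",
              nrow(object$components), nrow(sig), object$alpha))
  invisible(object$components)
}
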