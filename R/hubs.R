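# Hub detection from cost-averaged degree and betweenness centrality.
#
# Each hub measure is averaged over a grid of costs spanning the
# small-world regime (default 0.05-0.3 in steps of 0.01), standardized to
# z-scores across nodes, and tested one-sided against the standard normal:
# a node is a hub when p = 1 - Phi(z) < 0.05.

#' Cost-averaged nodal hub measures
#'
#' Thresholds the connectivity matrix at every cost of the grid and
#' averages each node's degree and betweenness centrality across the
#' resulting binary graphs.
#'
#' @param conn connectivity matrix or `fc_connectivity`.
#' @param grid cost values (default `seq(0.05, 0.3, 0.01)`).
#' @return data.frame: node, mean_degree, mean_bc.
#' @export
cost_averaged_metrics <- function(conn, grid = seq(0.05, 0.3, by = 0.01)) {
  stopifnot(length(grid) >= 1)
  m <- unclass_conn(conn)
  per_cost <- lapply(grid, function(cost) {
    g <- threshold_at_cost(m, cost)
    cbind(node_degree(g), betweenness_centrality(g))
  })
  avg <- Reduce(`+`, per_cost) / length(per_cost)
  nodes <- rownames(m) %||% paste0("V", seq_len(nrow(m)))
  data.frame(node = nodes, mean_degree = avg[, 1], mean_bc = avg[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided z-test for hub status
#'
#' Standardizes per-node metric values across nodes (sample SD, n - 1
#' denominator) and flags nodes with `p = 1 - pnorm(z) < alpha` as hubs.
#'
#' @param values per-node metric means (>= 3 nodes).
#' @param alpha significance level (default 0.05).
#' @return data.frame: value, z, p, hub.  With zero dispersion across
#'   nodes, z and p are NA, no node is a hub, and the result carries
#'   `attr(, "zero_dispersion") = TRUE`.
#' @export
hub_z_test <- function(values, alpha = 0.05) {
  v <- as.numeric(values)
  if (length(v) < 3) stopf("need at least 3 nodes")
  s <- stats::sd(v)
  if (s == 0) {
    out <- data.frame(value = v, z = NA_real_, p = NA_real_, hub = FALSE)
    attr(out, "zero_dispersion") <- TRUE
    return(out)
  }
  z <- (v - mean(v)) / s
  p <- 1 - stats::pnorm(z)
  data.frame(value = v, z = z, p = p, hub = p < alpha)
}

#' Detect network hubs
#'
#' Combines [cost_averaged_metrics()] and [hub_z_test()] for the two hub
#' measures and reports hub status by degree, by betweenness centrality,
#' and their union and intersection.
#'
#' @inheritParams cost_averaged_metrics
#' @param alpha significance level (default 0.05).
#' @return data.frame: node, mean_degree, z_degree, p_degree, hub_degree,
#'   mean_bc, z_bc, p_bc, hub_bc, hub_union, hub_both.
#' @export
detect_hubs <- function(conn, grid = seq(0.05, 0.3, by = 0.01),
                        alpha = 0.05) {
  cm <- cost_averaged_metrics(conn, grid)
  zd <- hub_z_test(cm$mean_degree, alpha)
  zb <- hub_z_test(cm$mean_bc, alpha)
  data.frame(node = cm$node,
             mean_degree = cm$mean_degree, z_degree = zd$z,
             p_degree = zd$p, hub_degree = zd$hub,
             mean_bc = cm$mean_bc, z_bc = zb$z, p_bc = zb$p,
             hub_bc = zb$hub,
             hub_union = zd$hub | zb$hub, hub_both = zd$hub & zb$hub,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a hub table as TSV
#' @param hubs data.frame from [detect_hubs()].
#' @param path output path.
#' @param group optional group label column to add.
#' @export
write_hub_table <- function(hubs, path, group = NULL) {
  if (!is.null(group)) hubs$group <- group
  utils::write.table(hubs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
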