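# Small cohort specs used across tests to keep runtimes down; the
# full-size study conditions (22 vs 22, 68 nodes, 150 frames) are
# exercised in the acceptance suite.

small_spec <- function(effect_size = 0, seed = 1, n_per_group = 6,
                       n_nodes = 16, n_frames = 64, ...) {
  cohort_spec(n_per_group = n_per_group, n_nodes = n_nodes,
              n_frames = n_frames,
              base_network = default_base_network(n_nodes, n_modules = 2),
              effect_size = effect_size, seed = seed, ...)
}

# fc_edge_stats object from a raw symmetric t matrix, for component tests
edge_stats_from_matrix <- function(tm, df = 10) {
  n <- nrow(tm)
  structure(list(t = tm, df = df, nodes = paste0("V", seq_len(n)),
                 n_a = 6, n_b = 6), class = "fc_edge_stats")
}

symmetric_t_matrix <- function(n, entries) {
  tm <- matrix(0, n, n)
  for (e in entries) {
    tm[e[1], e[2]] <- e[3]
    tm[e[2], e[1]] <- e[3]
  }
  diag(tm) <- NA
  tm
}
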