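# Synthetic two-group cohort generator.
#
# Emulates the study design the pipeline targets: two groups of 22
# subjects, 68 ROIs, 150 frames at TR = 2 s, with a connected subnetwork of
# edges whose latent correlation is attenuated in the patient group.  Each
# subject's ROI signals follow a stationary first-order autoregressive
# process whose innovations are multivariate normal with the target
# correlation structure, so the population cross-correlation of the
# signals equals the target correlation exactly and sample correlations
# converge to it with increasing frame count.

#' Specify a synthetic cohort
#'
#' @param n_per_group subjects per group (default 22).
#' @param n_nodes number of ROIs (default 68).
#' @param n_frames frames per subject (default 150; must be >= 32 so
#'   wavelet scale 4 is computable).
#' @param tr_seconds repetition time (default 2).
#' @param base_network target correlation matrix in \[0,1\] shared by both
#'   groups off the planted edges (default: modular structure, see
#'   [default_base_network()]).
#' @param planted_edges two-column matrix of node pairs whose correlation
#'   is attenuated in the patient group; must be edges of `base_network`
#'   and form a single connected component (default: a 7-edge tree, see
#'   [default_planted_edges()]).
#' @param effect_size attenuation in \[0,1\]: planted correlations are
#'   multiplied by `1 - effect_size` in the patient group.
#' @param ar_coef AR(1) coefficient of the observation process.
#' @param innovation_scale innovation standard deviation.
#' @param task_amplitude amplitude of an optional boxcar block-design mean
#'   term added to every node (default 0: connectivity, not activation, is
#'   the analysis target).
#' @param block_seconds task/rest block length for the boxcar (default 30).
#' @param covariate_model per-group covariate distributions; see
#'   [default_covariate_model()].
#' @param seed integer RNG seed; generation is a pure function of it.
#' @return an object of class `fc_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 22, n_nodes = 68, n_frames = 150,
                        tr_seconds = 2,
                        base_network = default_base_network(n_nodes),
                        planted_edges = default_planted_edges(),
                        effect_size = 0.8, ar_coef = 0.3,
                        innovation_scale = 1, task_amplitude = 0,
                        block_seconds = 30,
                        covariate_model = default_covariate_model(),
                        seed = 1L) {
  stopifnot(n_per_group >= 1, n_nodes >= 2, n_frames >= 32, tr_seconds > 0,
            effect_size >= 0, effect_size <= 1, abs(ar_coef) < 1,
            innovation_scale > 0)
  base_network <- as.matrix(base_network)
  if (nrow(base_network) != n_nodes || ncol(base_network) != n_nodes)
    stopf("base_network must be %d x %d", n_nodes, n_nodes)
  if (max(abs(base_network - t(base_network))) > 1e-12)
    stopf("base_network must be symmetric")
  diag(base_network) <- 1
  planted_edges <- as.matrix(planted_edges)
  if (ncol(planted_edges) != 2) stopf("planted_edges must have two columns")
  planted_edges <- t(apply(planted_edges, 1, sort))
  if (any(planted_edges[, 1] == planted_edges[, 2]) ||
      any(planted_edges > n_nodes) || any(planted_edges < 1))
    stopf("planted_edges must be valid off-diagonal node pairs")
  w <- base_network[planted_edges]
  if (any(w <= 0))
    stopf("planted edges must be edges of base_network (positive weight)")
  if (!edges_connected(planted_edges))
    stopf("planted_edges must form a single connected component")
  # ensure the base correlation is positive definite (repair if barely not)
  ev <- eigen(base_network, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    base_network <- as.matrix(Matrix::nearPD(base_network, corr = TRUE)$mat)
    warning("base_network repaired to the nearest correlation matrix")
  }
  structure(list(n_per_group = n_per_group, n_nodes = n_nodes,
                 n_frames = n_frames, tr_seconds = tr_seconds,
                 base_network = base_network, planted_edges = planted_edges,
                 effect_size = effect_size, ar_coef = ar_coef,
                 innovation_scale = innovation_scale,
                 task_amplitude = task_amplitude,
                 block_seconds = block_seconds,
                 covariate_model = covariate_model, seed = as.integer(seed)),
            class = "fc_cohort_spec")
}

edges_connected <- function(edges) {
  nodes <- sort(unique(as.vector(edges)))
  ig <- igraph::graph_from_edgelist(
    matrix(match(edges, nodes), ncol = 2), directed = FALSE)
  igraph::count_components(ig) == 1
}

#' Default modular base correlation network
#'
#' Block structure of `n_modules` equally sized modules with higher
#' within-module than between-module correlation, a coarse stand-in for
#' the community structure of cortical functional networks.
#'
#' @param n_nodes number of nodes.
#' @param n_modules number of modules (default 4).
#' @param r_within within-module correlation (default 0.3).
#' @param r_between between-module correlation (default 0.1).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
default_base_network <- function(n_nodes = 68, n_modules = 4,
                                 r_within = 0.3, r_between = 0.1) {
  module <- rep(seq_len(n_modules), length.out = n_nodes)
  module <- sort(module)
  m <- matrix(r_between, n_nodes, n_nodes)
  same <- outer(module, module, `==`)
  m[same] <- r_within
  diag(m) <- 1
  m
}

#' Default planted subnetwork
#'
#' A 7-edge tree over nodes 1--8 (all inside the first module of
#' [default_base_network()]), the connected component whose edges are
#' attenuated in the patient group.
#'
#' @return two-column integer matrix of node pairs.
#' @export
default_planted_edges <- function() {
  cbind(i = c(1, 1, 2, 2, 3, 3, 3),
        j = c(2, 3, 4, 5, 6, 7, 8))
}

#' Default covariate distributions
#'
#' Group-wise means and SDs for age, IQ and DSM T-scores, and the
#' proportion of males, chosen to resemble a two-group child cohort
#' (patients with elevated symptom T-scores).  DSM scores are drawn
#' independently of the planted connectivity effect.
#'
#' @return nested list: `$control` and `$patient`, each with `age`, `iq`
#'   (mean, sd), `p_male`, and `dsm` (3 x 2 matrix of mean, sd for
#'   inattentive, hyperactive, total).
#' @export
default_covariate_model <- function() {
  list(
    control = list(age = c(12.1, 2.23), iq = c(114.7, 14.92), p_male = 10 / 22,
                   dsm = rbind(inattentive = c(46.4, 6.61),
                               hyperactive = c(44.6, 4.75),
                               total = c(45.2, 5.33))),
    patient = list(age = c(11.6, 2.86), iq = c(106.6, 16.21), p_male = 12 / 22,
                   dsm = rbind(inattentive = c(75.3, 10.80),
                               hyperactive = c(70.6, 8.27),
                               total = c(74.7, 8.91)))
  )
}

# group covariance: base for controls; planted entries attenuated for patients
group_sigma <- function(spec, group) {
  s <- spec$base_network
  if (group == "patient" && spec$effect_size > 0) {
    idx <- spec$planted_edges
    s[idx] <- s[idx] * (1 - spec$effect_size)
    s[idx[, c(2, 1), drop = FALSE]] <- s[idx]
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10)
      stopf(paste("attenuating the planted edges by effect_size = %.2f makes",
                  "the patient correlation matrix non-positive-definite",
                  "(min eigenvalue %.3g)"), spec$effect_size, min(ev))
  }
  s
}

# one subject: stationary AR(1) with MVN innovations of correlation sigma
simulate_subject <- function(spec, chol_sigma) {
  burn <- 25L
  nf <- spec$n_frames + burn
  e <- matrix(stats::rnorm(nf * spec$n_nodes, sd = spec$innovation_scale),
              nf, spec$n_nodes) %*% chol_sigma
  x <- stats::filter(e, spec$ar_coef, method = "recursive")
  x <- as.matrix(x)[(burn + 1):nf, , drop = FALSE]
  if (spec$task_amplitude != 0) {
    block_frames <- max(1L, round(spec$block_seconds / spec$tr_seconds))
    boxcar <- rep(rep(c(1, 0), each = block_frames),
                  length.out = spec$n_frames)
    x <- x + spec$task_amplitude * boxcar
  }
  t(x)  # nodes x frames
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject ROI time-series from the group-specific latent
#' correlation structure defined by the spec, together with demographic and
#' clinical covariates and the ground truth of the planted effect.
#'
#' @param spec an `fc_cohort_spec` from [cohort_spec()].
#' @return list with `timeseries` (list of [roi_timeseries()] objects,
#'   controls first), `design` (data.frame: subject_id, group, age, sex,
#'   IQ, dsm_inattentive, dsm_hyperactive, dsm_total), and `truth` (list:
#'   `planted_edges`, `group_assignment`, `sigma_control`,
#'   `sigma_patient`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fc_cohort_spec"))
  sig <- list(control = group_sigma(spec, "control"),
              patient = group_sigma(spec, "patient"))
  chol_sig <- lapply(sig, chol)
  nodes <- paste0("ROI", sprintf("%02d", seq_len(spec$n_nodes)))
  with_seed(spec$seed, {
    groups <- rep(c("control", "patient"), each = spec$n_per_group)
    ids <- sprintf("S%03d", seq_along(groups))
    ts <- lapply(seq_along(groups), function(s) {
      v <- simulate_subject(spec, chol_sig[[groups[s]]])
      rownames(v) <- nodes
      roi_timeseries(v, nodes, spec$tr_seconds, subject_id = ids[s])
    })
    cov <- lapply(seq_along(groups), function(s) {
      cm <- spec$covariate_model[[groups[s]]]
      data.frame(
        subject_id = ids[s], group = groups[s],
        age = round(stats::rnorm(1, cm$age[1], cm$age[2]), 1),
        sex = ifelse(stats::runif(1) < cm$p_male, "M", "F"),
        IQ = round(stats::rnorm(1, cm$iq[1], cm$iq[2])),
        dsm_inattentive = round(stats::rnorm(1, cm$dsm["inattentive", 1],
                                             cm$dsm["inattentive", 2]), 1),
        dsm_hyperactive = round(stats::rnorm(1, cm$dsm["hyperactive", 1],
                                             cm$dsm["hyperactive", 2]), 1),
        dsm_total = round(stats::rnorm(1, cm$dsm["total", 1],
                                       cm$dsm["total", 2]), 1),
        stringsAsFactors = FALSE)
    })
    design <- do.call(rbind, cov)
    truth <- list(planted_edges = spec$planted_edges,
                  group_assignment = stats::setNames(groups, ids),
                  sigma_control = sig$control, sigma_patient = sig$patient)
    list(timeseries = ts, design = design, truth = truth)
  })
}

#' Generate a synthetic realignment trace
#'
#' Smooth low-frequency drift (moving-average-smoothed random walk) plus
#' sparse motion spikes, in the six-parameter rigid-body dialect (three
#' rotations in radians, then three translations in mm).  Rotation drift is
#' scaled so that its arc length on a 50 mm sphere matches the translation
#' drift scale.
#'
#' @param n_frames number of frames.
#' @param spike_prob per-frame probability of a motion spike.
#' @param spike_scale spike amplitude (mm).
#' @param drift_scale per-frame drift step SD (mm; 0 for no drift).
#' @param seed integer RNG seed.
#' @return an `fc_motion_trace` (see [motion_trace()]).
#' @export
generate_motion_trace <- function(n_frames, spike_prob = 0.02,
                                  spike_scale = 0.5, drift_scale = 0.02,
                                  seed = NULL) {
  stopifnot(n_frames >= 2, spike_prob >= 0, spike_prob <= 1)
  with_seed(seed, {
    smooth_walk <- function(scale) {
      if (scale == 0) return(rep(0, n_frames))
      w <- cumsum(stats::rnorm(n_frames + 10, sd = scale))
      as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))[6:(n_frames + 5)]
    }
    trans <- sapply(1:3, function(i) smooth_walk(drift_scale))
    rot <- sapply(1:3, function(i) smooth_walk(drift_scale / 50))
    spikes <- matrix(stats::runif(n_frames * 3) < spike_prob, n_frames, 3)
    trans <- trans + spikes * spike_scale *
      matrix(sample(c(-1, 1), n_frames * 3, replace = TRUE), n_frames, 3)
    motion_trace(cbind(rot, trans))
  })
}

#' Generate a benchmark graph family
#'
#' Canonical graph families used to validate the small-world machinery:
#' ring lattices (maximally regular), Erdős–Rényi graphs (random),
#' Watts–Strogatz graphs (small-world), and degree-matched rewirings of a
#' ring lattice.
#'
#' @param kind one of `"ring_lattice"`, `"erdos_renyi"`,
#'   `"watts_strogatz"`, `"matched_random"`.
#' @param n_nodes number of nodes.
#' @param mean_degree mean degree (must be even for lattice-based kinds and
#'   less than `n_nodes`).
#' @param rewire_prob rewiring probability (Watts–Strogatz only).
#' @param seed integer RNG seed.
#' @return an `fc_graph`.
#' @export
generate_benchmark_graph <- function(kind = c("ring_lattice", "erdos_renyi",
                                              "watts_strogatz",
                                              "matched_random"),
                                     n_nodes, mean_degree, rewire_prob = 0.1,
                                     seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(mean_degree >= 1, mean_degree < n_nodes)
  n_edges <- n_nodes * mean_degree / 2
  if (n_edges != round(n_edges))
    stopf("infeasible degree sequence: n_nodes * mean_degree must be even")
  if (kind %in% c("ring_lattice", "watts_strogatz", "matched_random") &&
      mean_degree %% 2 != 0)
    stopf("mean_degree must be even for %s", kind)
  switch(kind,
    ring_lattice = ring_lattice_nk(n_nodes, n_edges),
    erdos_renyi = with_seed(seed, binary_graph(as.matrix(
      igraph::as_adjacency_matrix(igraph::sample_gnm(n_nodes, n_edges))))),
    watts_strogatz = with_seed(seed, binary_graph(as.matrix(
      igraph::as_adjacency_matrix(igraph::sample_smallworld(
        1, n_nodes, mean_degree / 2, rewire_prob))))),
    matched_random = matched_random_graph(
      ring_lattice_nk(n_nodes, n_edges), seed = seed))
}

#' Connectivity matrix consistent with a binary graph
#'
#' Embeds a binary graph in a synthetic connectivity matrix: edges receive
#' strong weights and non-edges weak ones, with uniform jitter to break
#' ties, so that thresholding at the graph's own cost recovers the graph
#' exactly.  Used to feed known topologies through the cost-thresholding
#' pipeline.
#'
#' @param g an `fc_graph`.
#' @param edge_range,nonedge_range weight ranges for edges / non-edges.
#' @param seed integer RNG seed.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
graph_connectivity <- function(g, edge_range = c(0.5, 1),
                               nonedge_range = c(0, 0.3), seed = NULL) {
  n <- g$n
  with_seed(seed, {
    m <- matrix(0, n, n)
    up <- upper.tri(m)
    w <- ifelse(g$adj[up],
                stats::runif(sum(up), edge_range[1], edge_range[2]),
                stats::runif(sum(up), nonedge_range[1], nonedge_range[2]))
    m[up] <- w
    m <- m + t(m)
    diag(m) <- 1
    dimnames(m) <- list(g$nodes, g$nodes)
    m
  })
}
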