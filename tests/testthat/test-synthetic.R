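# Synthetic cohort generator: determinism, ground truth, convergence

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(small_spec(effect_size = 0.5, seed = 42))
  b <- generate_cohort(small_spec(effect_size = 0.5, seed = 42))
  expect_identical(lapply(a$timeseries, `[[`, "values"),
                   lapply(b$timeseries, `[[`, "values"))
  expect_identical(a$design, b$design)
  c <- generate_cohort(small_spec(effect_size = 0.5, seed = 43))
  expect_false(identical(a$timeseries[[1]]$values, c$timeseries[[1]]$values))
})

test_that("group covariances differ only on the planted edges", {
  spec <- small_spec(effect_size = 0.7)
  coh <- generate_cohort(spec)
  delta <- coh$truth$sigma_control - coh$truth$sigma_patient
  planted <- rbind(spec$planted_edges, spec$planted_edges[, 2:1])
  mask <- matrix(FALSE, spec$n_nodes, spec$n_nodes)
  mask[planted] <- TRUE
  expect_true(all(delta[!mask] == 0))
  expect_true(all(delta[mask] > 0))
  expect_equal(coh$truth$sigma_patient[spec$planted_edges],
               coh$truth$sigma_control[spec$planted_edges] * 0.3)
})

test_that("sample correlations converge to the base network with frame count", {
  frob_err <- function(n_frames) {
    spec <- small_spec(n_per_group = 1, n_nodes = 12, n_frames = n_frames,
                       seed = 7)
    coh <- generate_cohort(spec)
    controls <- coh$timeseries[coh$design$group == "control"]
    r <- stats::cor(t(controls[[1]]$values))
    norm(r - spec$base_network[1:12, 1:12], "F")
  }
  e_short <- frob_err(250)
  e_long <- frob_err(8000)
  expect_lt(e_long, e_short)
  expect_lt(e_long, 0.4)
})

test_that("with no planted effect, edge-wise t statistics center on zero", {
  tstats <- unlist(lapply(1:5, function(rep) {
    coh <- generate_cohort(small_spec(effect_size = 0, seed = 100 + rep))
    conns <- lapply(coh$timeseries, build_connectivity)
    ctrl <- coh$design$group == "control"
    st <- edgewise_t(conns[ctrl], conns[!ctrl])
    st$t[upper.tri(st$t)]
  }))
  expect_lt(abs(mean(tstats)), 0.1)
})

test_that("invalid constructions are rejected", {
  # planted pair absent from the base network
  base <- diag(10)
  expect_error(cohort_spec(n_nodes = 10, base_network = base,
                           planted_edges = cbind(1, 2)),
               "edges of base_network")
  # planted edges not forming one connected component
  expect_error(small_spec(planted_edges = cbind(c(1, 5), c(2, 6))),
               "connected")
  # attenuation that destroys positive definiteness
  tight <- default_base_network(16, n_modules = 2, r_within = 0.9)
  expect_error(
    generate_cohort(cohort_spec(n_nodes = 16, n_frames = 64,
                                base_network = tight, effect_size = 1,
                                n_per_group = 2)),
    "positive-definite")
  expect_error(cohort_spec(n_frames = 20), "n_frames")
})

test_that("covariates resemble the two-group design", {
  coh <- generate_cohort(cohort_spec(seed = 5))
  d <- coh$design
  expect_equal(nrow(d), 44)
  expect_equal(sum(d$group == "control"), 22)
  # symptom scores are clearly elevated in the patient group
  expect_gt(mean(d$dsm_total[d$group == "patient"]),
            mean(d$dsm_total[d$group == "control"]) + 15)
  expect_true(all(d$sex %in% c("M", "F")))
})

test_that("motion traces are seeded, spike-free when asked, and can trip QC", {
  z <- generate_motion_trace(50, spike_prob = 0, drift_scale = 0, seed = 1)
  expect_equal(framewise_displacement(z), rep(0, 49))
  a <- generate_motion_trace(80, seed = 9)
  b <- generate_motion_trace(80, seed = 9)
  expect_identical(a$params, b$params)
  spiky <- generate_motion_trace(80, spike_prob = 0.5, spike_scale = 2.0,
                                 seed = 4)
  expect_true(apply_exclusion(motion_summary(spiky), spiky)$excluded)
})

test_that("benchmark graph families are well-formed and seeded", {
  ring <- generate_benchmark_graph("ring_lattice", 10, 2)
  expect_true(all(node_degree(ring) == 2))
  expect_equal(local_efficiency(ring), 0)  # C10 neighbors are non-adjacent
  e1 <- generate_benchmark_graph("erdos_renyi", 30, 4, seed = 3)
  e2 <- generate_benchmark_graph("erdos_renyi", 30, 4, seed = 3)
  expect_identical(e1$adj, e2$adj)
  mr <- generate_benchmark_graph("matched_random", 20, 4, seed = 2)
  expect_equal(sort(node_degree(mr)), sort(node_degree(
    generate_benchmark_graph("ring_lattice", 20, 4))), ignore_attr = TRUE)
  expect_error(generate_benchmark_graph("ring_lattice", 10, 3), "even")
  expect_error(generate_benchmark_graph("erdos_renyi", 9, 5), "even")
})

test_that("graph_connectivity embeds a graph recoverable at its own cost", {
  g <- generate_benchmark_graph("erdos_renyi", 20, 4, seed = 6)
  conn <- graph_connectivity(g, seed = 7)
  back <- threshold_at_cost(conn, graph_cost(g))
  expect_identical(back$adj, g$adj)
})

test_that("a written cohort reloads through the manifest reader", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_spec(seed = 3, n_per_group = 2))
  write_cohort(coh, dir)
  design <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(design$subject_id, coh$design$subject_id)
  ts <- read_timeseries_tsv(file.path(dir, "timeseries", "S001.tsv"), tr = 2)
  expect_equal(ts$values, coh$timeseries[[1]]$values, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(truth$planted_edges, nrow(coh$truth$planted_edges))
})
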