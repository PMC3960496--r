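# Pipeline orchestration: configuration, file I/O, and the end-to-end run
# simulate/QC -> connectivity -> topology -> hubs -> NBS -> group stats.

#' Read the node-definition table
#'
#' Tab-separated table of ROI definitions (region label, hemisphere, peak
#' MNI coordinates in mm, sphere radius, peak Z).  The packaged default is
#' the 68-ROI visual-attention node set.
#'
#' @param path TSV path; default the packaged 68-node table.
#' @return data.frame with a unique `node` label column
#'   (hemisphere + region).
#' @export
read_node_table <- function(path = system.file("extdata",
                                               "node_table_68.tsv",
                                               package = "fcnet")) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  need <- c("region", "hemisphere", "x", "y", "z", "radius_mm", "peak_z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("node table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$node <- paste(df$hemisphere, df$region, sep = ". ")
  if (anyDuplicated(df$node)) {
    dup <- unique(df$node[duplicated(df$node)])
    stopf("duplicate node label(s): %s", paste(dup, collapse = ", "))
  }
  df
}

#' Write a node table as TSV
#' @param node_table data.frame from [read_node_table()].
#' @param path output path.
#' @export
write_node_table <- function(node_table, path) {
  node_table$node <- NULL
  utils::write.table(node_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' TSV with columns subject_id, group (control/patient), age, sex, IQ,
#' dsm_inattentive, dsm_hyperactive, dsm_total.
#'
#' @param path file path.
#' @return validated design data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  bad <- which(!df$group %in% c("control", "patient"))
  if (length(bad))
    stopf("%s: unknown group label in row(s) %s", path,
          paste(bad, collapse = ", "))
  check_design(df)
  df
}

#' @rdname read_manifest
#' @param design design data.frame to write.
#' @export
write_manifest <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ground truth of a synthetic cohort as JSON
#' @param truth `truth` element of [generate_cohort()] output.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    planted_edges = unname(apply(truth$planted_edges, 1, as.integer,
                                 simplify = FALSE)),
    group_assignment = as.list(truth$group_assignment)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-subject time-series TSVs, motion-parameter files, a manifest
#' TSV and a ground-truth JSON into `dir`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param motion_seed base seed for the per-subject motion traces.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, motion_seed = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (i in seq_along(cohort$timeseries)) {
    ts <- cohort$timeseries[[i]]
    write_timeseries_tsv(ts, file.path(dir, "timeseries",
                                       paste0(ts$subject_id, ".tsv")))
    tr <- generate_motion_trace(ts$n_frames, seed = motion_seed + i)
    write_motion_par(tr, file.path(dir, "motion",
                                   paste0(ts$subject_id, ".par")))
  }
  write_manifest(cohort$design, file.path(dir, "manifest.tsv"))
  write_ground_truth(cohort$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default; all
#' randomness is controlled by explicit per-stage seeds derived from
#' `seed`.
#'
#' @param data_dir directory holding `manifest.tsv`, `timeseries/` and
#'   `motion/` (as written by [write_cohort()]); NULL to simulate.
#' @param output_dir where artifacts are written (NULL: nothing written).
#' @param tr_seconds repetition time.
#' @param scales wavelet scales averaged into the connectivity matrix.
#' @param filter,boundary wavelet settings (see [modwt_details()]).
#' @param cost_grid_global cost grid for the small-world regime and global
#'   curve comparisons (default 0.1 to 0.5 by 0.01).
#' @param cost_grid_hubs cost grid for hub and nodal-efficiency averaging
#'   (default 0.05 to 0.3 by 0.01).
#' @param n_null random-null ensemble size per cost.
#' @param nbs_t_threshold,nbs_n_perm NBS settings.
#' @param alpha significance level used throughout.
#' @param param_limit,mean_motion_limit motion exclusion limits (mm).
#' @param seed master integer seed.
#' @param cohort an `fc_cohort_spec` used when `data_dir` is NULL.
#' @return an object of class `fc_config` (a named list).
#' @export
pipeline_config <- function(data_dir = NULL, output_dir = NULL,
                            tr_seconds = 2, scales = 2:4, filter = "la8",
                            boundary = "periodic",
                            cost_grid_global = seq(0.1, 0.5, by = 0.01),
                            cost_grid_hubs = seq(0.05, 0.3, by = 0.01),
                            n_null = 20, nbs_t_threshold = 3.5,
                            nbs_n_perm = 10000, alpha = 0.05,
                            param_limit = 1.0, mean_motion_limit = 0.25,
                            seed = 1L, cohort = NULL) {
  structure(list(data_dir = data_dir, output_dir = output_dir,
                 tr_seconds = tr_seconds, scales = scales, filter = filter,
                 boundary = boundary, cost_grid_global = cost_grid_global,
                 cost_grid_hubs = cost_grid_hubs, n_null = n_null,
                 nbs_t_threshold = nbs_t_threshold, nbs_n_perm = nbs_n_perm,
                 alpha = alpha, param_limit = param_limit,
                 mean_motion_limit = mean_motion_limit,
                 seed = as.integer(seed), cohort = cohort),
            class = "fc_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return an `fc_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  # hash the analysis parameters only: where data live and where results
  # go does not change what was computed
  flat <- config[setdiff(names(config),
                         c("cohort", "data_dir", "output_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(flat),
                   vapply(flat, function(v) paste(format(v), collapse = ","),
                          ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Loads (or simulates) a cohort, applies motion QC exclusions, builds the
#' per-subject wavelet connectivity matrices, characterizes the
#' small-world topology of the group-mean networks, detects hubs, runs
#' the NBS group comparison and the covariate-adjusted group statistics,
#' and assembles a consolidated report.  Deterministic given the config.
#'
#' @param config an `fc_config` from [pipeline_config()].
#' @param verbose print stage progress (default TRUE).
#' @return an object of class `fc_pipeline_report` (a named list; see the
#'   elements of the returned object).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "fc_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- Sys.time()

  # --- load or simulate -----------------------------------------------
  if (is.null(config$data_dir)) {
    spec <- config$cohort %||% cohort_spec(seed = config$seed)
    say("stage simulate: %d + %d subjects, %d nodes, %d frames",
        spec$n_per_group, spec$n_per_group, spec$n_nodes, spec$n_frames)
    cohort <- generate_cohort(spec)
    ts_list <- cohort$timeseries
    design <- cohort$design
    truth <- cohort$truth
    motion <- lapply(seq_along(ts_list), function(i)
      generate_motion_trace(ts_list[[i]]$n_frames,
                            seed = config$seed * 1000L + i))
  } else {
    design <- read_manifest(file.path(config$data_dir, "manifest.tsv"))
    say("stage load: %d subjects from %s", nrow(design), config$data_dir)
    ts_list <- lapply(design$subject_id, function(id)
      read_timeseries_tsv(file.path(config$data_dir, "timeseries",
                                    paste0(id, ".tsv")),
                          tr = config$tr_seconds, subject_id = id))
    motion <- lapply(design$subject_id, function(id) {
      p <- file.path(config$data_dir, "motion", paste0(id, ".par"))
      if (file.exists(p)) read_motion_par(p, id) else NULL
    })
    truth <- NULL
  }

  # --- motion QC -------------------------------------------------------
  qc <- lapply(seq_along(motion), function(i) {
    if (is.null(motion[[i]]))
      return(data.frame(subject_id = design$subject_id[i],
                        mean_motion = NA_real_, max_param_mm = NA_real_,
                        excluded = FALSE, reasons = ""))
    s <- motion_summary(motion[[i]])
    dec <- apply_exclusion(s, motion[[i]], config$param_limit,
                           config$mean_motion_limit)
    data.frame(subject_id = design$subject_id[i],
               mean_motion = s$mean_motion, max_param_mm = s$max_param_mm,
               excluded = dec$excluded,
               reasons = paste(dec$reasons, collapse = ";"))
  })
  qc <- do.call(rbind, qc)
  keep <- !qc$excluded
  for (i in which(!keep))
    say("stage qc: excluding %s (%s)", qc$subject_id[i], qc$reasons[i])
  say("stage qc: %d/%d subjects retained", sum(keep), nrow(qc))
  ts_list <- ts_list[keep]
  design <- design[keep, , drop = FALSE]

  # --- connectivity ----------------------------------------------------
  say("stage connectivity: wavelet scales %s",
      paste(config$scales, collapse = ","))
  conns <- lapply(ts_list, build_connectivity, scales = config$scales,
                  filter = config$filter, boundary = config$boundary)
  is_ctrl <- design$group == "control"
  conn_ctrl <- conns[is_ctrl]
  conn_pat <- conns[!is_ctrl]
  group_mean_conn <- function(cs) {
    m <- Reduce(`+`, lapply(cs, unclass_conn)) / length(cs)
    m
  }
  mean_conn <- list(control = group_mean_conn(conn_ctrl),
                    patient = group_mean_conn(conn_pat))

  # --- topology --------------------------------------------------------
  say("stage topology: %d costs, %d nulls each",
      length(config$cost_grid_global), config$n_null)
  regimes <- lapply(mean_conn, small_world_regime,
                    grid = config$cost_grid_global, n_null = config$n_null,
                    seed = config$seed + 17L)
  # per-subject profiles over the global grid, and nodal efficiency /
  # degree distribution over the hub grid
  profile_of <- function(conn) {
    vapply(config$cost_grid_global, function(cost) {
      g <- threshold_at_cost(conn, cost)
      c(global_efficiency(g), local_efficiency(g))
    }, numeric(2))
  }
  profiles <- lapply(conns, profile_of)
  eglob_mat <- t(vapply(profiles, function(p) p[1, ],
                        numeric(length(config$cost_grid_global))))
  eloc_mat <- t(vapply(profiles, function(p) p[2, ],
                       numeric(length(config$cost_grid_global))))
  colnames(eglob_mat) <- colnames(eloc_mat) <- config$cost_grid_global
  nodal <- t(vapply(conns, function(conn) {
    rowMeans(vapply(config$cost_grid_hubs, function(cost)
      nodal_efficiency(threshold_at_cost(conn, cost)),
      numeric(nrow(unclass_conn(conn)))))
  }, numeric(nrow(unclass_conn(conns[[1]])))))
  colnames(nodal) <- conns[[1]]$nodes
  degree_fit <- lapply(mean_conn, function(m) {
    degs <- rowMeans(vapply(config$cost_grid_hubs, function(cost)
      node_degree(threshold_at_cost(m, cost)), numeric(nrow(m))))
    fit_truncated_power_law(round(degs), k_max = nrow(m) - 1)
  })

  # --- hubs ------------------------------------------------------------
  say("stage hubs: cost grid %.2f-%.2f", min(config$cost_grid_hubs),
      max(config$cost_grid_hubs))
  hubs <- lapply(mean_conn, detect_hubs, grid = config$cost_grid_hubs,
                 alpha = config$alpha)

  # --- NBS -------------------------------------------------------------
  say("stage nbs: t > %.2f, %d permutations", config$nbs_t_threshold,
      config$nbs_n_perm)
  nbs <- nbs_permutation(conn_ctrl, conn_pat,
                         t_threshold = config$nbs_t_threshold,
                         n_perm = config$nbs_n_perm,
                         seed = config$seed + 41L, alpha = config$alpha)

  # --- group statistics ------------------------------------------------
  say("stage stats: ANCOVA with age, IQ, sex; FDR at %.2f", config$alpha)
  curves <- list(
    e_glob = compare_global_curves(eglob_mat, design, alpha = config$alpha),
    e_loc = compare_global_curves(eloc_mat, design, alpha = config$alpha))
  nodal_stats <- nodal_group_comparison(nodal, design, alpha = config$alpha)
  pat <- design$group == "patient"
  clin <- clinical_regression(
    nodal[pat, , drop = FALSE],
    design[pat, intersect(c("dsm_inattentive", "dsm_hyperactive"),
                          names(design)), drop = FALSE],
    alpha = config$alpha)

  report <- structure(list(
    config_hash = config_hash(config), seed = config$seed,
    qc = qc, design = design,
    n_nodes = length(conns[[1]]$nodes),
    n_pairs = n_pairs(conns[[1]]),
    mean_connectivity = mean_conn,
    small_world = regimes, degree_fit = degree_fit, hubs = hubs,
    nbs = nbs, curves = curves, nodal_stats = nodal_stats,
    clinical = clin, nodal_efficiency = nodal, truth = truth,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "fc_pipeline_report")

  if (!is.null(config$output_dir)) write_report(report, config)
  report
}

#' @export
print.fc_pipeline_report <- function(x, ...) {
  cat(sprintf("<fc_pipeline_report> %d subjects (%d excluded by QC), %d nodes, %d pairs\n",
              nrow(x$design), sum(x$qc$excluded), x$n_nodes, x$n_pairs))
  for (g in names(x$small_world)) {
    r <- x$small_world[[g]]$regime
    cat(sprintf("  %s small-world regime: %s\n", g,
                if (is.null(r)) "none"
                else sprintf("[%.2f, %.2f]", r[["lo"]], r[["hi"]])))
  }
  sig <- x$nbs$components[x$nbs$components$significant, , drop = FALSE]
  cat(sprintf("  NBS: %d significant component(s)\n", nrow(sig)))
  invisible(x)
}

# write the per-stage artifacts and the consolidated JSON report
write_report <- function(report, config) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$qc, file.path(out, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in names(report$hubs))
    write_hub_table(report$hubs[[g]], file.path(out,
                                                paste0("hubs_", g, ".tsv")),
                    group = g)
  utils::write.table(report$nodal_stats, file.path(out, "nodal_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$clinical, file.path(out, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_nbs_result(report$nbs, file.path(out, "nbs"))
  payload <- list(
    config_hash = report$config_hash, seed = report$seed,
    n_nodes = report$n_nodes, n_pairs = report$n_pairs,
    qc_excluded = report$qc$subject_id[report$qc$excluded],
    small_world_regime = lapply(report$small_world,
                                function(s) s$regime %||% NA),
    degree_fit = lapply(report$degree_fit, function(f)
      list(alpha = f$alpha, kc = f$kc, converged = f$converged)),
    hubs = lapply(report$hubs, function(h) h$node[h$hub_union]),
    nbs_components = report$nbs$components,
    significant_cost_ranges = lapply(report$curves, `[[`, "ranges"))
  jsonlite::write_json(payload, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
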