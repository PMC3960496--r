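# Group inference: covariate-adjusted comparisons of topology metrics,
# FDR correction, and nodal-efficiency vs clinical-score regressions.

check_design <- function(design) {
  need <- c("subject_id", "group", "age", "sex", "IQ")
  miss <- setdiff(need, names(design))
  if (length(miss)) stopf("design is missing column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(design$group), c("control", "patient"))
  if (length(bad)) stopf("unknown group label(s): %s",
                         paste(bad, collapse = ", "))
  if (anyDuplicated(design$subject_id)) stopf("duplicate subject ids")
  design$group <- factor(design$group, levels = c("control", "patient"))
  design$sex <- factor(design$sex)
  design
}

#' Covariate-adjusted group comparison of a metric
#'
#' Partial F-test for the group term in the least-squares model
#' `metric ~ group + age + IQ + sex` (sex as a fixed-effect indicator).
#'
#' @param values per-subject metric, aligned with the rows of `design`.
#' @param design cohort design data.frame with columns subject_id, group
#'   (control/patient), age, sex, IQ.
#' @param covariates covariate column names (default age, IQ, sex).
#' @return list with `F`, `df1`, `df2`, `p`, and the group-coefficient
#'   `estimate` (patient minus control, adjusted).
#' @export
ancova_metric <- function(values, design, covariates = c("age", "IQ", "sex")) {
  design <- check_design(design)
  v <- as.numeric(values)
  if (length(v) != nrow(design))
    stopf("values (%d) do not match design rows (%d)", length(v),
          nrow(design))
  if (anyNA(design[covariates])) stopf("missing covariate values")
  # constant covariates carry no information: drop them so the model
  # degrades gracefully to the unadjusted two-sample comparison
  keep <- vapply(covariates, function(cv)
    length(unique(design[[cv]])) > 1, logical(1))
  covariates <- covariates[keep]
  dat <- cbind(data.frame(.y = v, group = design$group),
               design[covariates])
  full <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(full))) {
    aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
    stopf("collinear design; aliased term(s): %s",
          paste(aliased, collapse = ", "))
  }
  red <- stats::lm(.y ~ . - group, data = dat)
  av <- stats::anova(red, full)
  list(F = av$F[2], df1 = av$Df[2], df2 = av$Res.Df[2],
       p = av$`Pr(>F)`[2],
       estimate = unname(stats::coef(full)["grouppatient"]))
}

#' Benjamini--Hochberg FDR decisions
#'
#' Step-up false discovery rate control: rejects every hypothesis whose
#' BH-adjusted p-value is at most `alpha`.
#'
#' @param pvalues numeric p-values in \[0, 1\] (NA allowed, never rejected).
#' @param alpha FDR level (default 0.05).
#' @return list with `reject` (logical), `p_adjusted`.
#' @export
fdr_correct <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(reject = !is.na(adj) & adj <= alpha, p_adjusted = adj)
}

#' Nodal metric group comparison with FDR across nodes
#'
#' Applies [ancova_metric()] to every node's metric and corrects across
#' nodes with BH FDR.
#'
#' @param nodal matrix, subjects x nodes (e.g. nodal efficiencies averaged
#'   over the small-world regime).
#' @param design cohort design (see [ancova_metric()]).
#' @param alpha FDR level.
#' @inheritParams ancova_metric
#' @return data.frame: node, F, df1, df2, p, p_fdr, significant, estimate.
#' @export
nodal_group_comparison <- function(nodal, design,
                                   covariates = c("age", "IQ", "sex"),
                                   alpha = 0.05) {
  nodal <- as.matrix(nodal)
  res <- lapply(seq_len(ncol(nodal)), function(j)
    ancova_metric(nodal[, j], design, covariates))
  out <- data.frame(
    node = colnames(nodal) %||% paste0("V", seq_len(ncol(nodal))),
    F = vapply(res, `[[`, 0, "F"),
    df1 = vapply(res, `[[`, 0, "df1"),
    df2 = vapply(res, `[[`, 0, "df2"),
    p = vapply(res, `[[`, 0, "p"),
    estimate = vapply(res, `[[`, 0, "estimate"),
    row.names = NULL, stringsAsFactors = FALSE)
  fdr <- fdr_correct(out$p, alpha)
  out$p_fdr <- fdr$p_adjusted
  out$significant <- fdr$reject
  out
}

#' Nodal efficiency vs clinical score regressions
#'
#' Per node and score, the least-squares regression of nodal efficiency on
#' the score (slope per T-score unit, model F, p), with BH FDR across
#' nodes within each score.  Run in the patient group only.
#'
#' @param nodal_eff matrix, subjects x nodes.
#' @param scores data.frame, subjects x scores (same row order).
#' @param alpha FDR level.
#' @return data.frame: node, score, slope, F, p, p_fdr, significant,
#'   defined (FALSE when the score has zero variance).
#' @export
clinical_regression <- function(nodal_eff, scores, alpha = 0.05) {
  nodal_eff <- as.matrix(nodal_eff)
  if (nrow(nodal_eff) < 3) stopf("need at least 3 subjects")
  if (nrow(nodal_eff) != nrow(scores))
    stopf("nodal_eff and scores have different subject counts")
  nodes <- colnames(nodal_eff) %||% paste0("V", seq_len(ncol(nodal_eff)))
  out <- list()
  for (sc in names(scores)) {
    s <- as.numeric(scores[[sc]])
    if (stats::sd(s) == 0) {
      res <- data.frame(node = nodes, score = sc, slope = NA_real_,
                        F = NA_real_, p = NA_real_, p_fdr = NA_real_,
                        significant = FALSE, defined = FALSE,
                        stringsAsFactors = FALSE)
    } else {
      fits <- lapply(seq_along(nodes), function(j) {
        fit <- stats::lm(nodal_eff[, j] ~ s)
        sm <- summary(fit)
        c(slope = unname(stats::coef(fit)[2]),
          F = sm$fstatistic[["value"]],
          p = stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                        sm$fstatistic[["dendf"]], lower.tail = FALSE))
      })
      res <- data.frame(node = nodes, score = sc,
                        slope = vapply(fits, `[[`, 0, "slope"),
                        F = vapply(fits, `[[`, 0, "F"),
                        p = vapply(fits, `[[`, 0, "p"),
                        stringsAsFactors = FALSE)
      fdr <- fdr_correct(res$p, alpha)
      res$p_fdr <- fdr$p_adjusted
      res$significant <- fdr$reject
      res$defined <- TRUE
    }
    out[[sc]] <- res
  }
  if (!length(out))
    return(data.frame(node = character(0), score = character(0),
                      slope = numeric(0), F = numeric(0), p = numeric(0),
                      p_fdr = numeric(0), significant = logical(0),
                      defined = logical(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Group comparison of global efficiency curves across costs
#'
#' Runs the covariate-adjusted group comparison at every cost of a common
#' grid, corrects across costs with BH FDR, and reports contiguous
#' significant cost ranges.
#'
#' @param profiles matrix, subjects x costs, of one global metric
#'   (e.g. local efficiency per cost); column names give the cost grid.
#' @param design cohort design.
#' @param grid cost values (default parsed from column names).
#' @param alpha FDR level.
#' @inheritParams ancova_metric
#' @return list with `table` (per cost: F, p, p_fdr, significant) and
#'   `ranges` (data.frame of contiguous significant cost intervals).
#' @export
compare_global_curves <- function(profiles, design, grid = NULL,
                                  covariates = c("age", "IQ", "sex"),
                                  alpha = 0.05) {
  profiles <- as.matrix(profiles)
  design <- check_design(design)
  if (nrow(profiles) != nrow(design))
    stopf("profiles (%d rows) do not match design (%d subjects)",
          nrow(profiles), nrow(design))
  if (nrow(design) < 2 || length(unique(design$group)) < 2 ||
      min(table(design$group)) < 2)
    stopf("need at least 2 subjects per group")
  grid <- grid %||% as.numeric(colnames(profiles))
  if (anyNA(grid) || length(grid) != ncol(profiles))
    stopf("cost grid mismatch with profile columns")
  res <- lapply(seq_along(grid), function(j)
    ancova_metric(profiles[, j], design, covariates))
  tab <- data.frame(cost = grid,
                    F = vapply(res, `[[`, 0, "F"),
                    p = vapply(res, `[[`, 0, "p"),
                    estimate = vapply(res, `[[`, 0, "estimate"))
  fdr <- fdr_correct(tab$p, alpha)
  tab$p_fdr <- fdr$p_adjusted
  tab$significant <- fdr$reject
  ranges <- significant_ranges(grid, tab$significant)
  list(table = tab, ranges = ranges)
}

significant_ranges <- function(grid, sig) {
  if (!any(sig)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(lo = grid[starts[keep]], hi = grid[ends[keep]])
}

#' Demographic comparison table
#'
#' Two-sample Welch t-tests for numeric covariates and a chi-square test
#' for sex, for cohort reporting.
#'
#' @param design cohort design data.frame.
#' @param vars numeric columns to compare (default age, IQ and DSM scores
#'   present in the design).
#' @return data.frame: measure, statistic, value, p.
#' @export
demographic_table <- function(design,
                              vars = intersect(c("age", "IQ",
                                                 "dsm_inattentive",
                                                 "dsm_hyperactive",
                                                 "dsm_total"),
                                               names(design))) {
  design <- check_design(design)
  rows <- lapply(vars, function(v) {
    tt <- stats::t.test(design[[v]] ~ design$group)
    data.frame(measure = v, statistic = "t", value = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  ct <- suppressWarnings(stats::chisq.test(table(design$sex, design$group)))
  rows[[length(rows) + 1]] <- data.frame(measure = "sex", statistic = "chisq",
                                         value = unname(ct$statistic),
                                         p = ct$p.value,
                                         stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
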