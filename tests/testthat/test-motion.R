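# Frame-wise head-motion metrics and exclusion rules

trace_from_rows <- function(...) motion_trace(rbind(...))

test_that("FD is zero for a constant trace and matches the stated arithmetic", {
  const <- trace_from_rows(c(0.01, 0, 0, 1, 2, 3), c(0.01, 0, 0, 1, 2, 3),
                           c(0.01, 0, 0, 1, 2, 3))
  expect_equal(framewise_displacement(const), c(0, 0))
  # one step: translations (0.1, -0.1, 0.05) mm, rotations (0.001, 0,
  # -0.002) rad on a 50 mm sphere -> 0.25 + 50 * 0.003 = 0.40 mm
  tr <- trace_from_rows(rep(0, 6),
                        c(0.001, 0, -0.002, 0.1, -0.1, 0.05))
  expect_equal(framewise_displacement(tr, rotation_radius = 50), 0.40)
})

test_that("FD equals column-wise recomputation on random traces", {
  set.seed(21)
  p <- matrix(rnorm(30 * 6, sd = 0.1), 30, 6)
  fd <- framewise_displacement(motion_trace(p), rotation_radius = 50)
  manual <- rep(0, 29)
  for (col in 1:6) {
    scale <- if (col <= 3) 50 else 1
    manual <- manual + scale * abs(p[2:30, col] - p[1:29, col])
  }
  expect_equal(fd, manual, tolerance = 1e-12)
})

test_that("FD depends only on differentials and is monotone in the rotation radius", {
  set.seed(4)
  p <- matrix(rnorm(20 * 6, sd = 0.05), 20, 6)
  shifted <- sweep(p, 2, c(0.3, -0.1, 0.2, 5, -2, 1), `+`)
  expect_equal(framewise_displacement(motion_trace(p)),
               framewise_displacement(motion_trace(shifted)))
  fd0 <- framewise_displacement(motion_trace(p), rotation_radius = 0)
  expect_equal(fd0, rowSums(abs(diff(p[, 4:6]))))
  fd50 <- framewise_displacement(motion_trace(p), rotation_radius = 50)
  fd80 <- framewise_displacement(motion_trace(p), rotation_radius = 80)
  expect_true(all(fd80 >= fd50 & fd50 >= fd0))
})

test_that("mean motion uses the translational displacement norm", {
  expect_equal(mean_motion(trace_from_rows(rep(0, 6), rep(0, 6))), 0)
  # 3-4-5 triangle: displacement (0.03, 0.04, 0) -> 0.05 mm
  tr <- trace_from_rows(rep(0, 6), c(0, 0, 0, 0.03, 0.04, 0))
  expect_equal(mean_motion(tr), 0.05)
  set.seed(9)
  p <- matrix(rnorm(25 * 6, sd = 0.08), 25, 6)
  d <- diff(p[, 4:6])
  expect_equal(mean_motion(motion_trace(p)),
               mean(sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)))
  expect_equal(mean_motion(motion_trace(p), method = "per_axis"),
               mean(abs(d)))
})

test_that("single-frame traces are rejected", {
  tr <- motion_trace(matrix(0, 1, 6))
  expect_error(framewise_displacement(tr), "2 frames")
  expect_error(mean_motion(tr), "2 frames")
})

test_that("exclusion fires on mean motion above 0.25 mm", {
  # oscillating 0.26 mm translation steps: mean motion 0.26, all
  # parameters well below the 1.0 mm deviation limit
  p <- matrix(0, 10, 6)
  p[seq(2, 10, 2), 4] <- 0.26
  tr <- motion_trace(p)
  dec <- apply_exclusion(motion_summary(tr), tr)
  expect_true(dec$excluded)
  expect_equal(dec$reasons, "mean_motion")
})

test_that("exclusion fires on a >1.0 mm parameter excursion", {
  p <- matrix(0, 50, 6)
  p[25, 5] <- 1.2
  tr <- motion_trace(p)
  s <- motion_summary(tr)
  expect_lt(s$mean_motion, 0.25)
  dec <- apply_exclusion(s, tr)
  expect_true(dec$excluded)
  expect_equal(dec$reasons, "parameter_deviation")
  # rotations count after conversion: 0.03 rad * 50 mm = 1.5 mm
  p2 <- matrix(0, 50, 6)
  p2[10, 2] <- 0.03
  tr2 <- motion_trace(p2)
  expect_true(apply_exclusion(motion_summary(tr2), tr2)$excluded)
})

test_that("low-motion subjects are retained", {
  tr <- generate_motion_trace(150, spike_prob = 0, drift_scale = 0.005,
                              seed = 31)
  s <- motion_summary(tr)
  expect_lt(s$mean_motion, 0.25)
  expect_false(apply_exclusion(s, tr)$excluded)
})

test_that("motion-connectivity check recovers perfect and absent association", {
  x <- seq(0.02, 0.2, length.out = 20)
  res <- motion_connectivity_check(x, x)
  expect_equal(res$estimate[res$method == "pearson"], 1)
  expect_lt(res$p[res$method == "pearson"], 1e-10)
  # constant connectivity: undefined, flagged
  res0 <- motion_connectivity_check(x, rep(0.5, 20))
  expect_false(any(res0$defined))
  expect_error(motion_connectivity_check(x[1:2], x[1:2]), "3 subjects")
})

test_that("the linear check holds its nominal type-I error", {
  set.seed(77)
  hits <- replicate(500, {
    res <- motion_connectivity_check(rnorm(44), rnorm(44))
    res$p[res$method == "pearson"] < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("motion par files round-trip", {
  tr <- generate_motion_trace(40, seed = 12)
  path <- withr::local_tempfile(fileext = ".par")
  write_motion_par(tr, path)
  back <- read_motion_par(path)
  expect_equal(back$params, tr$params, tolerance = 1e-6)
})
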