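test_that("the default design yields 32 scans per timepoint and 192 records", {
  sim <- generate_cluster_dataset(seed = 1)
  r <- sim$dataset$records
  expect_equal(nrow(r), 192L)
  scans_per_tp <- table(r$timepoint[r$unit == "core"])
  expect_true(all(scans_per_tp == 32))
  expect_equal(unname(sim$dataset$design), c(3L, 2L, 2L, 8L))
})

test_that("the noise-free limit reproduces the cell means exactly", {
  truth <- synthetic_truth(sigma_day = 0, sigma_session = 0, sigma_scan = 0,
                           resid_sd = c(core = 0, control = 0),
                           motion_effect = 0)
  sim <- generate_cluster_dataset(truth, seed = 5)
  r <- sim$dataset$records
  for (tp in rownames(truth$cell_means)) {
    for (roi in colnames(truth$cell_means)) {
      vals <- r$thickness[r$timepoint == tp & r$unit == roi]
      expect_equal(vals, rep(truth$cell_means[tp, roi], length(vals)))
    }
  }
})

test_that("generation is deterministic in the seed", {
  a <- generate_cluster_dataset(seed = 42)$dataset
  b <- generate_cluster_dataset(seed = 42)$dataset
  c <- generate_cluster_dataset(seed = 43)$dataset
  expect_identical(a$records, b$records)
  expect_false(isTRUE(all.equal(a$records$thickness, c$records$thickness)))
})

test_that("random effects are shared across the two ROI rows of a scan", {
  truth <- synthetic_truth(resid_sd = c(core = 0, control = 0),
                           motion_effect = 0)
  r <- generate_cluster_dataset(truth, seed = 9)$dataset$records
  # with zero residual noise, (thickness - cell mean) must be identical for
  # the core and control rows of every scan
  dev <- r$thickness - truth$cell_means[cbind(as.character(r$timepoint), r$unit)]
  key <- paste(r$timepoint, r$day, r$session, r$scan)
  per_scan <- tapply(dev, key, function(v) diff(range(v)))
  expect_lt(max(per_scan), 1e-12)
})

test_that("empirical variance decomposition tracks the generating components", {
  truth <- synthetic_truth(motion_effect = 0)
  # many days so each stratum is well estimated
  r <- generate_cluster_dataset(truth, design = c(1, 300, 2, 4),
                                seed = 21)$dataset$records
  dev <- r$thickness - truth$cell_means[cbind(as.character(r$timepoint), r$unit)]
  core <- r$unit == "core"
  key <- paste(r$day, r$session, r$scan)
  # residuals: core-minus-control within a scan removes all shared effects
  d <- dev[core][order(key[core])] - dev[!core][order(key[!core])]
  expect_equal(stats::var(d), truth$resid_sd[["core"]]^2 + truth$resid_sd[["control"]]^2,
               tolerance = 0.15)
  # scan level: variance of within-session differences of scan means
  scan_mean <- tapply(dev, key, mean)  # scan effect + mean residual
  sess_of <- tapply(paste(r$day, r$session), key, `[`, 1)
  within <- unlist(tapply(scan_mean, sess_of, function(v) v - mean(v)))
  mean_resid_var <- (truth$resid_sd[["core"]]^2 + truth$resid_sd[["control"]]^2) / 4
  # within-session centering of m scans scales variance by (m-1)/m
  expect_equal(stats::var(within) * 4 / 3, truth$sigma_scan^2 + mean_resid_var,
               tolerance = 0.15)
})

test_that("the synthetic normative cohort matches its declared composition", {
  co <- generate_normative_cohort(seed = 2)
  expect_equal(length(co$age), 25L)
  expect_equal(sum(co$sex), 13L)

  exact <- generate_normative_cohort(n = 30, n_male = 15, resid_sd = 0,
                                     true_beta = c(2.5, -0.01, 0.05),
                                     n_units = 3, seed = 3)
  pred <- 2.5 - 0.01 * exact$age + 0.05 * exact$sex
  for (j in 1:3) expect_equal(exact$thickness[, j], pred,
                              ignore_attr = TRUE)
  expect_error(generate_normative_cohort(resid_sd = -1), "resid_sd")
  expect_error(generate_normative_cohort(n = 10, n_male = 11), "n_male")
})

test_that("fit_normative recovers the generating plane on a large cohort", {
  co <- generate_normative_cohort(n = 200, n_male = 100, resid_sd = 0.1,
                                  true_beta = c(2.5, -0.01, 0.05),
                                  n_units = 2, seed = 7)
  m <- fit_normative(co)
  # envelopes from 100 repeated simulations (99% quantile of |error|):
  # beta0 0.25, beta1 0.0036, beta2 0.048
  expect_lt(max(abs(m$beta1 - (-0.01))), 0.02)
  expect_lt(max(abs(m$beta2 - 0.05)), 0.05)
  expect_lt(max(abs(m$beta0 - 2.5)), 0.3)
})

test_that("vertex datasets honour their noise-free and null limits", {
  mesh <- make_grid_mesh(4, 5)
  nv <- mesh$n_vertices
  truth0 <- synthetic_truth(sigma_day = 0, sigma_session = 0, sigma_scan = 0,
                            motion_effect = 0)
  vt <- vertex_truth(rep(2, nv), rep(0.05, nv))
  vd <- generate_vertex_dataset(vt, truth0, mesh, design = c(3, 1, 1, 2),
                                noise_sd = 0, seed = 4)
  for (tp_i in 1:3) {
    rows <- vd$scans$timepoint == rownames(truth0$cell_means)[tp_i]
    expect_equal(unname(vd$thickness[rows, ]),
                 matrix(2 - (tp_i - 1) * 0.05, sum(rows), nv))
  }
  # no decline: timepoint means agree at every vertex (up to noise-free exactness)
  vt0 <- vertex_truth(rep(2.2, nv), rep(0, nv))
  vd0 <- generate_vertex_dataset(vt0, truth0, mesh, design = c(3, 1, 1, 4),
                                 noise_sd = 0, seed = 4)
  tp_means <- apply(vd0$thickness, 2, tapply, vd0$scans$timepoint, mean)
  expect_lt(max(apply(tp_means, 2, function(v) diff(range(v)))), 1e-12)
  expect_error(generate_vertex_dataset(vertex_truth(rep(2, 7), rep(0, 7)),
                                       truth0, mesh), "sized to the mesh")
})

test_that("neighbour-averaging passes induce spatial noise correlation", {
  mesh <- make_grid_mesh(12, 12)
  truth0 <- synthetic_truth(sigma_day = 0, sigma_session = 0, sigma_scan = 0,
                            motion_effect = 0)
  vt_raw <- vertex_truth(rep(2, 144), rep(0, 144), spatial_corr_steps = 0L)
  vt_sm <- vertex_truth(rep(2, 144), rep(0, 144), spatial_corr_steps = 5L)
  lag1_corr <- function(vd) {
    x <- vd$thickness
    e <- mesh$edges + 1L
    mean(vapply(seq_len(nrow(e)), function(i)
      stats::cor(x[, e[i, 1]], x[, e[i, 2]]), numeric(1)))
  }
  vd_raw <- generate_vertex_dataset(vt_raw, truth0, mesh,
                                    design = c(1, 1, 1, 100), seed = 6)
  vd_sm <- generate_vertex_dataset(vt_sm, truth0, mesh,
                                   design = c(1, 1, 1, 100), seed = 6)
  expect_lt(abs(lag1_corr(vd_raw)), 0.15)
  expect_gt(lag1_corr(vd_sm), 0.5)
})

test_that("synthetic motion traces encode drift, jumps, and rotations", {
  still <- generate_motion_trace(10, drift_per_tr = 0)
  expect_equal(max(abs(still$translations)), 0)
  for (k in 1:10) expect_equal(still$rotations[, , k], diag(3))

  drift <- generate_motion_trace(65, drift_per_tr = 0.1)
  expect_equal(rms_displacement(drift$rotations[, , 65],
                                drift$translations[65, ]), 6.4)

  rot <- generate_motion_trace(5, rotation_per_tr = 2)
  expect_equal(max(abs(rot$translations)), 0)
  ang <- acos((sum(diag(rot$rotations[, , 5])) - 1) / 2) * 180 / pi
  expect_equal(ang, 8, tolerance = 1e-8)

  jumped <- generate_motion_trace(10, drift_per_tr = 0, jump = c(4, 2))
  expect_equal(jumped$translations[4, 1], 0)
  expect_equal(jumped$translations[5, 1], 2)
})
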