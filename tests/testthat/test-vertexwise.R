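make_vertex_frame <- function(truth, decline = 0.02, baseline = 2.0,
                              noise_sd = 0.01, design = c(3, 2, 2, 8),
                              seed = 1) {
  mesh <- make_grid_mesh(1, 2)
  vt <- vertex_truth(rep(baseline, 2), rep(decline, 2))
  vd <- generate_vertex_dataset(vt, truth, mesh, design = design,
                                noise_sd = noise_sd, seed = seed)
  cbind(vd$scans, thickness = vd$thickness[, 1])
}

test_that("the cascade is deterministic and reaches the fixed-only model on degenerate data", {
  # noise present but zero day/session/scan variance: both random models are
  # singular, so the cascade must land on the fixed-effects-only model
  truth0 <- synthetic_truth(sigma_day = 0, sigma_session = 0, sigma_scan = 0,
                            motion_effect = 0)
  vf <- make_vertex_frame(truth0, noise_sd = 0.02, seed = 3)
  res1 <- fit_vertex_cascade(vf, timepoint_levels = c("BL", "M3", "M6"))
  res2 <- fit_vertex_cascade(vf, timepoint_levels = c("BL", "M3", "M6"))
  expect_equal(res1$model_code, 0L)
  expect_equal(res2$model_code, res1$model_code)
  expect_equal(res1$fit$beta, res2$fit$beta)
})

test_that("clear day/session variance keeps the nested model", {
  truth_big <- synthetic_truth(sigma_day = 0.08, sigma_session = 0.06,
                               sigma_scan = 0.01, motion_effect = 0)
  codes <- vapply(1:5, function(s) {
    vf <- make_vertex_frame(truth_big, noise_sd = 0.01,
                            seed = derive_seed(900, s))
    fit_vertex_cascade(vf, timepoint_levels = c("BL", "M3", "M6"))$model_code
  }, integer(1))
  expect_gte(mean(codes == 2L), 0.8)
})

test_that("change maps apply the dual-threshold significance rule", {
  truth <- synthetic_truth(motion_effect = 0)
  mesh <- make_grid_mesh(2, 3)
  vt <- vertex_truth(rep(2.0, 6), rep(0.02, 6))
  vd <- generate_vertex_dataset(vt, truth, mesh, design = c(3, 2, 2, 6),
                                noise_sd = 0.01, seed = 5)
  vm <- vertex_change_maps(vd$thickness, vd$scans,
                           timepoint_levels = c("BL", "M3", "M6"))
  expect_equal(nrow(vm), 6 * 3)
  expect_true(all(vm$model_code %in% 0:2))
  # the printed per-pair threshold is .017 = round(.05 / 3, 3)
  expect_equal(round(0.05 / 3, 3), 0.017)
  expect_equal(vm$significant,
               vm$p_main < 0.05 & vm$p_pair < 0.05 / 3)
  # a uniform 0.02 mm decline per interval on a 2.0 mm baseline is about -1%
  # per step and -2% over two steps
  bl_m6 <- vm$percent_change[vm$pair == "BL - M6"]
  expect_equal(mean(bl_m6), -100 * 0.04 / 2.0, tolerance = 0.25)
  bl_m3 <- vm$percent_change[vm$pair == "BL - M3"]
  expect_equal(mean(bl_m3), -100 * 0.02 / 2.0, tolerance = 0.35)
})

test_that("a null decline map yields few significant vertices", {
  truth <- synthetic_truth(motion_effect = 0)
  mesh <- make_grid_mesh(4, 5)
  vt <- vertex_truth(rep(2.2, 20), rep(0, 20))
  vd <- generate_vertex_dataset(vt, truth, mesh, design = c(3, 2, 2, 4),
                                noise_sd = 0.02, seed = 8)
  vm <- vertex_change_maps(vd$thickness, vd$scans,
                           timepoint_levels = c("BL", "M3", "M6"))
  expect_lte(mean(vm$significant, na.rm = TRUE), 0.1)
})

test_that("vertex EMMs aggregated over a mask approximate the ROI-level estimate", {
  truth <- synthetic_truth(motion_effect = 0)
  mesh <- make_grid_mesh(2, 2)
  vt <- vertex_truth(rep(1.8, 4), rep(0.02, 4))
  vd <- generate_vertex_dataset(vt, truth, mesh, design = c(3, 2, 2, 8),
                                noise_sd = 0.01, seed = 11)
  # ROI-level route: average vertices per scan, then model
  roi_thickness <- rowMeans(vd$thickness)
  records <- data.frame(participant = "p", timepoint = vd$scans$timepoint,
                        day = vd$scans$day, session = vd$scans$session,
                        scan = vd$scans$scan, unit_type = "roi", unit = "core",
                        thickness = roi_thickness, motion = vd$scans$motion,
                        stringsAsFactors = FALSE)
  ds <- cluster_scan_dataset(records, timepoint_levels = c("BL", "M3", "M6"))
  fit_roi <- fit_lme(ds, random = "scan", strata = "none")
  emm_roi <- estimated_marginal_means(fit_roi)

  # vertex route: fit each vertex, average the EMMs
  vertex_emms <- sapply(0:3, function(v) {
    vf <- cbind(vd$scans, thickness = vd$thickness[, v + 1])
    res <- fit_vertex_cascade(vf, timepoint_levels = c("BL", "M3", "M6"))
    estimated_marginal_means(res$fit)$emm
  })
  expect_equal(rowMeans(vertex_emms), emm_roi$emm, tolerance = 0.005)
})

test_that("missing vertices are explicit gaps, not zeros", {
  truth <- synthetic_truth(motion_effect = 0)
  mesh <- make_grid_mesh(1, 2)
  vt <- vertex_truth(rep(2, 2), rep(0.02, 2))
  vd <- generate_vertex_dataset(vt, truth, mesh, design = c(3, 2, 2, 4),
                                noise_sd = 0.01, seed = 13)
  # poison one vertex so that every model errors out (non-finite data)
  vd$thickness[, 2] <- NA_real_
  vm <- vertex_change_maps(vd$thickness, vd$scans,
                           timepoint_levels = c("BL", "M3", "M6"))
  v1 <- vm[vm$vertex == 1, ]
  expect_true(all(is.na(v1$percent_change)))
  expect_true(all(is.na(v1$model_code)))
  v0 <- vm[vm$vertex == 0, ]
  expect_false(any(is.na(v0$percent_change)))
})
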