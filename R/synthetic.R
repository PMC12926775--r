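# Synthetic-data generators with known ground truth. The defaults emulate
# the study design the package targets: 3 timepoints x 2 days x 2
# sessions/day x 8 scans/session (32 scans per timepoint), a core ROI
# declining by a few hundredths of a millimetre over 3-6 months while a
# sensorimotor control ROI stays nearly flat, and a normative cohort of 25
# controls (age 67.4 +- 4.8, 13 men / 12 women).

#' Ground truth for a synthetic cluster-scan dataset
#'
#' The default cell means follow the published svPPA-like pattern: core ROI
#' 1.780 / 1.760 / 1.739 mm at baseline / 3 months / 6 months (a 0.041-mm
#' 6-month decline) and a control ROI at 2.350 / 2.3499 / 2.340 mm. Default
#' variance components (`sigma_day = sigma_session = 0.004`,
#' `sigma_scan = 0.01`, residual SD 0.012 mm core / 0.020 mm control) give
#' single-scan errors of roughly 1-2%, in line with the test-retest
#' literature for FreeSurfer cortical thickness.
#'
#' @param cell_means Matrix of mm cell means, timepoints x ROIs, with
#'   dimnames; rows are timepoints in order, columns `core` and `control`.
#' @param sigma_day,sigma_session,sigma_scan Random-intercept SDs in mm.
#' @param resid_sd Named residual SD per ROI stratum (mm).
#' @param motion_effect Fixed-effect slope on centered motion, mm per
#'   (mm/min). Default -0.001 (slightly thinner apparent cortex with more
#'   motion).
#' @param motion_meanlog,motion_sdlog Log-scale parameters of the lognormal
#'   per-scan motion-score distribution (default `log(3)` and 0.5, so a small
#'   tail exceeds the 10 mm/min exclusion threshold).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(cell_means = default_cell_means(),
                            sigma_day = 0.004,
                            sigma_session = 0.004,
                            sigma_scan = 0.01,
                            resid_sd = c(core = 0.012, control = 0.02),
                            motion_effect = -0.001,
                            motion_meanlog = log(3),
                            motion_sdlog = 0.5) {
  cell_means <- as.matrix(cell_means)
  cs_assert(!is.null(rownames(cell_means)) && !is.null(colnames(cell_means)),
            "cell_means needs timepoint rownames and ROI colnames")
  cs_assert(all(cell_means > 0), "cell means must be positive (mm)")
  for (s in c(sigma_day, sigma_session, sigma_scan, resid_sd)) {
    cs_assert(is.finite(s) && s >= 0, "all SDs must be non-negative")
  }
  cs_assert(all(colnames(cell_means) %in% names(resid_sd)),
            "resid_sd must name every ROI column of cell_means")
  structure(list(cell_means = cell_means, sigma_day = sigma_day,
                 sigma_session = sigma_session, sigma_scan = sigma_scan,
                 resid_sd = resid_sd, motion_effect = motion_effect,
                 motion_meanlog = motion_meanlog, motion_sdlog = motion_sdlog),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @export
default_cell_means <- function() {
  matrix(c(1.780, 1.760, 1.739,
           2.350, 2.3499, 2.340),
         nrow = 3, ncol = 2,
         dimnames = list(c("BL", "M3", "M6"), c("core", "control")))
}

#' Generate a synthetic cluster-scan dataset
#'
#' Each scan receives day-, session- and scan-level random intercepts shared
#' across its two ROI rows (the scan, not the scan-by-ROI cell, is the
#' sampling unit), a lognormal motion score entering through
#' `motion_effect * (motion - E[motion])`, and ROI-stratum residual noise:
#' `thickness = cell_mean + b_day + b_session + b_scan +
#'  lambda * (motion - mu_motion) + e`.
#'
#' @param truth A [synthetic_truth()].
#' @param design Integer vector `(timepoints, days, sessions, scans)`;
#'   default `c(3, 2, 2, 8)` yields 32 scans per timepoint and 192 records.
#' @param participant Participant identifier.
#' @param seed Integer seed; same seed reproduces the dataset exactly.
#' @return A list with `dataset` (a [cluster_scan_dataset()]) and `truth`.
#' @export
generate_cluster_dataset <- function(truth = synthetic_truth(),
                                     design = c(3, 2, 2, 8),
                                     participant = "sim-01",
                                     seed = 1L) {
  cs_assert(inherits(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  cs_assert(length(design) == 4 && all(vapply(design, is_count, logical(1))),
            "design must be four positive counts")
  n_tp <- design[1]; n_day <- design[2]; n_sess <- design[3]; n_scan <- design[4]
  cs_assert(nrow(truth$cell_means) >= n_tp,
            "cell_means must cover every timepoint in the design")
  tp_levels <- rownames(truth$cell_means)[seq_len(n_tp)]
  rois <- colnames(truth$cell_means)

  set.seed(seed)
  grid <- expand.grid(scan = seq_len(n_scan), session = seq_len(n_sess),
                      day = seq_len(n_day), timepoint = seq_len(n_tp))
  grid <- grid[order(grid$timepoint, grid$day, grid$session, grid$scan), ]
  n_scans_total <- nrow(grid)

  day_key <- paste(grid$timepoint, grid$day)
  sess_key <- paste(day_key, grid$session)
  b_day <- stats::rnorm(length(unique(day_key)), 0, truth$sigma_day)
  b_sess <- stats::rnorm(length(unique(sess_key)), 0, truth$sigma_session)
  b_scan <- stats::rnorm(n_scans_total, 0, truth$sigma_scan)
  motion <- stats::rlnorm(n_scans_total, truth$motion_meanlog, truth$motion_sdlog)
  mu_motion <- exp(truth$motion_meanlog + truth$motion_sdlog^2 / 2)
  scan_effect <- b_day[match(day_key, unique(day_key))] +
    b_sess[match(sess_key, unique(sess_key))] + b_scan +
    truth$motion_effect * (motion - mu_motion)

  records <- do.call(rbind, lapply(seq_along(rois), function(j) {
    data.frame(
      participant = participant,
      timepoint = tp_levels[grid$timepoint],
      day = grid$day,
      session = grid$session,
      scan = sprintf("scan%02d", grid$scan),
      unit_type = "roi",
      unit = rois[j],
      thickness = truth$cell_means[cbind(grid$timepoint, j)] + scan_effect +
        stats::rnorm(n_scans_total, 0, truth$resid_sd[[rois[j]]]),
      motion = motion,
      stringsAsFactors = FALSE
    )
  }))
  list(dataset = cluster_scan_dataset(records, timepoint_levels = tp_levels),
       truth = truth)
}

#' Generate a synthetic normative control cohort
#'
#' Subject-level thickness per unit follows the generating plane
#' `beta0 + beta1 * age + beta2 * sex + noise`, with sex coded 0 = female,
#' 1 = male. Defaults mirror the normative cohort the method was developed
#' against: 25 subjects, age 67.4 +- 4.8 years, 13 men.
#'
#' @param n Number of subjects.
#' @param age_mean,age_sd Age distribution in years.
#' @param n_male Number of subjects with sex code 1.
#' @param true_beta Generating coefficients `c(beta0, beta1, beta2)` in mm,
#'   mm/year, mm.
#' @param resid_sd Residual SD in mm (>= 0).
#' @param n_units Number of thickness units (vertices or ROIs).
#' @param seed Integer seed.
#' @return An object of class `normative_cohort`: list with `age` (years),
#'   `sex` (0/1), `thickness` (n x n_units matrix, mm), and the generating
#'   `true_beta`/`resid_sd`.
#' @export
generate_normative_cohort <- function(n = 25, age_mean = 67.4, age_sd = 4.8,
                                      n_male = 13,
                                      true_beta = c(2.5, -0.01, 0.05),
                                      resid_sd = 0.1, n_units = 1,
                                      seed = 1L) {
  cs_assert(is_count(n, min = 1), "n must be a positive count")
  cs_assert(is_count(n_male, min = 0) && n_male <= n, "need n_male <= n")
  cs_assert(is.finite(resid_sd) && resid_sd >= 0, "resid_sd must be >= 0")
  cs_assert(length(true_beta) == 3, "true_beta must be (beta0, beta1, beta2)")
  set.seed(seed)
  age <- stats::rnorm(n, age_mean, age_sd)
  sex <- sample(rep(c(1L, 0L), c(n_male, n - n_male)))
  mu <- true_beta[1] + true_beta[2] * age + true_beta[3] * sex
  thickness <- matrix(mu, n, n_units) +
    matrix(stats::rnorm(n * n_units, 0, resid_sd), n, n_units)
  colnames(thickness) <- sprintf("unit%04d", seq_len(n_units) - 1L)
  structure(list(age = age, sex = sex, thickness = thickness,
                 true_beta = true_beta, resid_sd = resid_sd),
            class = "normative_cohort")
}

#' Ground truth for a synthetic vertex-level dataset
#'
#' @param baseline_map Positive baseline thickness per vertex (mm).
#' @param decline_map Non-negative per-interval decline per vertex (mm per
#'   timepoint step).
#' @param spatial_corr_steps Number of neighbour-averaging passes applied to
#'   the vertex noise, mimicking the spatial correlation left by upstream
#'   surface smoothing (0 = independent noise).
#' @return An object of class `vertex_truth`.
#' @export
vertex_truth <- function(baseline_map, decline_map,
                         spatial_corr_steps = 0L) {
  cs_assert(all(baseline_map > 0), "baseline_map must be positive")
  cs_assert(length(decline_map) == length(baseline_map),
            "decline_map must match baseline_map in length")
  cs_assert(is_count(spatial_corr_steps, min = 0),
            "spatial_corr_steps must be a non-negative count")
  structure(list(baseline_map = as.numeric(baseline_map),
                 decline_map = as.numeric(decline_map),
                 spatial_corr_steps = as.integer(spatial_corr_steps)),
            class = "vertex_truth")
}

#' Generate per-scan vertex thickness matrices
#'
#' Each scan's vertex map is `baseline - (timepoint_index - 1) * decline +
#' shared scan-level offset + spatially smoothed noise`, where the scan-level
#' offset carries the same day/session/scan hierarchy as the ROI generator
#' and the noise is iid Gaussian passed through `spatial_corr_steps`
#' neighbour-averaging smoothing passes on the mesh.
#'
#' @param vtruth A [vertex_truth()] sized to the mesh.
#' @param truth A [synthetic_truth()] providing variance components, motion
#'   distribution and motion slope.
#' @param mesh A [mesh_graph()].
#' @param design Integer vector `(timepoints, days, sessions, scans)`.
#' @param noise_sd Vertex-level residual SD in mm before smoothing.
#' @param seed Integer seed.
#' @return A list with `thickness` (scans x vertices matrix), `scans`
#'   (data frame of per-scan covariates: timepoint, day, session, scan,
#'   motion), `mesh`, and the two truth objects.
#' @export
generate_vertex_dataset <- function(vtruth, truth = synthetic_truth(),
                                    mesh, design = c(3, 2, 2, 8),
                                    noise_sd = 0.012, seed = 1L) {
  cs_assert(inherits(vtruth, "vertex_truth"), "vtruth must be a vertex_truth")
  cs_assert(inherits(mesh, "mesh_graph"), "mesh must be a mesh_graph")
  cs_assert(length(vtruth$baseline_map) == mesh$n_vertices,
            "vertex maps must be sized to the mesh (%d vertices)", mesh$n_vertices)
  n_tp <- design[1]; n_day <- design[2]; n_sess <- design[3]; n_scan <- design[4]
  set.seed(seed)
  grid <- expand.grid(scan = seq_len(n_scan), session = seq_len(n_sess),
                      day = seq_len(n_day), timepoint = seq_len(n_tp))
  grid <- grid[order(grid$timepoint, grid$day, grid$session, grid$scan), ]
  n_scans_total <- nrow(grid)
  day_key <- paste(grid$timepoint, grid$day)
  sess_key <- paste(day_key, grid$session)
  b_day <- stats::rnorm(length(unique(day_key)), 0, truth$sigma_day)
  b_sess <- stats::rnorm(length(unique(sess_key)), 0, truth$sigma_session)
  b_scan <- stats::rnorm(n_scans_total, 0, truth$sigma_scan)
  motion <- stats::rlnorm(n_scans_total, truth$motion_meanlog, truth$motion_sdlog)
  mu_motion <- exp(truth$motion_meanlog + truth$motion_sdlog^2 / 2)
  offset <- b_day[match(day_key, unique(day_key))] +
    b_sess[match(sess_key, unique(sess_key))] + b_scan +
    truth$motion_effect * (motion - mu_motion)

  nv <- mesh$n_vertices
  neighbours <- vertex_neighbours(mesh)
  thickness <- matrix(0, n_scans_total, nv)
  for (s in seq_len(n_scans_total)) {
    noise <- stats::rnorm(nv, 0, noise_sd)
    noise <- smooth_vertex_map(noise, neighbours, vtruth$spatial_corr_steps)
    thickness[s, ] <- vtruth$baseline_map -
      (grid$timepoint[s] - 1) * vtruth$decline_map + offset[s] + noise
  }
  colnames(thickness) <- sprintf("v%d", seq_len(nv) - 1L)
  scans <- data.frame(
    timepoint = rownames(truth$cell_means)[grid$timepoint],
    day = grid$day, session = grid$session,
    scan = sprintf("scan%02d", grid$scan),
    motion = motion, stringsAsFactors = FALSE
  )
  list(thickness = thickness, scans = scans, mesh = mesh,
       vertex_truth = vtruth, truth = truth)
}

vertex_neighbours <- function(mesh) {
  nb <- vector("list", mesh$n_vertices)
  e <- mesh$edges + 1L
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
    nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
  }
  nb
}

smooth_vertex_map <- function(x, neighbours, steps) {
  for (s in seq_len(steps)) {
    x <- vapply(seq_along(x), function(v) mean(x[c(v, neighbours[[v]])]), numeric(1))
  }
  x
}

#' Generate a synthetic rigid-motion trace
#'
#' Transform `k` (1-based, relative to the first TR) encodes a cumulative
#' translation of `(k - 1) * drift_per_tr` mm along the x-axis (plus an
#' optional step `jump` after a given TR index) and a cumulative rotation of
#' `(k - 1) * rotation_per_tr` degrees about the z-axis.
#'
#' @param n_tr Number of TRs (>= 2).
#' @param drift_per_tr Translation drift per TR in mm.
#' @param jump Optional `c(index, mm)`: an additional displacement applied
#'   after TR `index`.
#' @param rotation_per_tr Rotation increment per TR in degrees.
#' @param tr_duration TR duration in seconds (default 2.2).
#' @return A [motion_trace()].
#' @export
generate_motion_trace <- function(n_tr, drift_per_tr = 0, jump = NULL,
                                  rotation_per_tr = 0, tr_duration = 2.2) {
  cs_assert(is_count(n_tr, min = 2), "n_tr must be an integer >= 2")
  rotations <- array(0, dim = c(3, 3, n_tr))
  translations <- matrix(0, n_tr, 3)
  for (k in seq_len(n_tr)) {
    rotations[, , k] <- rotation_about_z((k - 1) * rotation_per_tr)
    tx <- (k - 1) * drift_per_tr
    if (!is.null(jump) && (k - 1) >= jump[1]) tx <- tx + jump[2]
    translations[k, 1] <- tx
  }
  motion_trace(rotations, translations, tr_duration = tr_duration)
}
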