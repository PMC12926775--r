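# Rigid-body motion quality control. Each scan carries a per-TR series of
# rigid transforms (estimated relative to the scan's first TR); displacement
# is summarized as the RMS movement of the points of a 64-mm sphere, and the
# per-scan score is RMS displacement per minute (RMSpm).

#' Construct a motion trace
#'
#' @param rotations `3 x 3 x n_tr` array of rotation matrices (orthonormal,
#'   det +1), each relative to the first TR.
#' @param translations `n_tr x 3` matrix of translations in mm.
#' @param tr_duration Duration of one TR in seconds.
#' @param scan_id Optional scan identifier carried into summaries.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(rotations, translations, tr_duration, scan_id = NULL) {
  translations <- as.matrix(translations)
  cs_assert(length(dim(rotations)) == 3 && all(dim(rotations)[1:2] == 3),
            "rotations must be a 3 x 3 x n_tr array")
  n_tr <- dim(rotations)[3]
  cs_assert(n_tr >= 2, "a motion trace needs at least 2 TRs")
  cs_assert(nrow(translations) == n_tr && ncol(translations) == 3,
            "translations must be n_tr x 3")
  cs_assert(is_number(tr_duration) && tr_duration > 0,
            "tr_duration must be a positive number of seconds")
  for (k in seq_len(n_tr)) check_rotation(rotations[, , k])
  structure(list(rotations = rotations, translations = translations,
                 tr_duration = tr_duration, n_tr = n_tr, scan_id = scan_id),
            class = "motion_trace")
}

check_rotation <- function(R, tol = 1e-6) {
  cs_assert(is.matrix(R) && all(dim(R) == 3), "rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    cs_abort("rotation part is not orthonormal with det +1")
  }
  invisible(R)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

#' RMS displacement of a rigid transform over a solid sphere
#'
#' Summarizes a rigid head movement as the root-mean-square displacement of
#' all points inside a sphere of radius `radius`, centered at `center`
#' (isocenter by default). For rotation `R` and translation `t`, with
#' `A = R - I`, the RMS over the solid sphere has the closed form
#' `sqrt(radius^2/5 * tr(A'A) + ||A c + t||^2)`, since the second moment of a
#' uniform solid sphere is `radius^2/5` per axis.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector in mm.
#' @param radius Sphere radius in mm (default 64).
#' @param center Sphere center (default the origin).
#' @return RMS displacement in mm.
#' @export
rms_displacement <- function(rotation, translation = c(0, 0, 0), radius = 64,
                             center = c(0, 0, 0)) {
  check_rotation(rotation)
  cs_assert(is_number(radius) && radius > 0, "radius must be positive")
  A <- rotation - diag(3)
  d0 <- as.numeric(A %*% center) + translation
  sqrt(radius^2 / 5 * sum(A * A) + sum(d0^2))
}

#' Per-scan RMS displacement per minute (RMSpm)
#'
#' Reduces a per-TR rigid motion trace to one motion score. The default
#' `"framewise"` mode measures, at each TR, the RMS sphere displacement of
#' the relative transform from the previous TR, sums these framewise steps,
#' and divides by the scan duration in minutes (a path length per minute, in
#' mm/min). The `"mean-to-first"` mode instead averages the per-TR RMS
#' displacements relative to the first TR and divides by the duration; both
#' readings of "displacement relative to the first TR, averaged over the
#' scan, per minute" are provided because the convention differs across
#' navigator-based motion pipelines.
#'
#' @param trace A [motion_trace()].
#' @param radius Sphere radius in mm passed to [rms_displacement()].
#' @param center Sphere center.
#' @param mode `"framewise"` (default) or `"mean-to-first"`.
#' @return An object of class `motion_summary`: list with `scan_id`,
#'   `rmspm` (mm/min), `displacement` (per-TR series, mm), `mode`,
#'   `duration_min`, and `excluded` (filled by [filter_scans()], `NA` here).
#' @export
compute_rmspm <- function(trace, radius = 64, center = c(0, 0, 0),
                          mode = c("framewise", "mean-to-first")) {
  cs_assert(inherits(trace, "motion_trace"), "trace must be a motion_trace")
  mode <- match.arg(mode)
  n <- trace$n_tr
  duration_min <- n * trace$tr_duration / 60
  cs_assert(duration_min > 0, "scan duration must be positive")
  if (mode == "framewise") {
    steps <- numeric(n - 1L)
    for (k in 2:n) {
      R_prev <- trace$rotations[, , k - 1L]
      R_k <- trace$rotations[, , k]
      R_rel <- R_k %*% t(R_prev)
      t_rel <- trace$translations[k, ] - as.numeric(R_rel %*% trace$translations[k - 1L, ])
      steps[k - 1L] <- rms_displacement(R_rel, t_rel, radius = radius, center = center)
    }
    rmspm <- sum(steps) / duration_min
    series <- c(0, cumsum(steps))
  } else {
    series <- vapply(seq_len(n), function(k) {
      rms_displacement(trace$rotations[, , k], trace$translations[k, ],
                       radius = radius, center = center)
    }, numeric(1))
    rmspm <- mean(series) / duration_min
  }
  structure(list(scan_id = trace$scan_id, rmspm = rmspm, displacement = series,
                 mode = mode, duration_min = duration_min, excluded = NA),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("Motion summary%s: RMSpm = %.3f mm/min (%s mode, %.2f min)\n",
              if (is.null(x$scan_id)) "" else paste0(" [", x$scan_id, "]"),
              x$rmspm, x$mode, x$duration_min))
  invisible(x)
}

#' Apply the motion exclusion rule to a dataset
#'
#' Removes all records of scans whose motion score is strictly greater than
#' `threshold` (mm/min) and reports discard counts per participant and
#' timepoint.
#'
#' @param dataset A [cluster_scan_dataset()] with motion scores on every scan.
#' @param threshold Exclusion threshold in mm/min (default 10; strict `>`).
#' @return A list with `dataset` (the filtered [cluster_scan_dataset()]) and
#'   `report` (data frame with per participant x timepoint scan counts,
#'   discards, and percentages, plus the threshold used).
#' @export
filter_scans <- function(dataset, threshold = 10) {
  cs_assert(inherits(dataset, "cluster_scan_dataset"),
            "dataset must be a cluster_scan_dataset")
  cs_assert(is_number(threshold) && threshold >= 0, "threshold must be non-negative")
  r <- dataset$records
  cs_assert(!anyNA(r$motion), "every scan needs a motion score before QC filtering")
  scan_key <- paste(r$participant, r$timepoint, r$day, r$session, r$scan, sep = "\r")
  scans <- r[!duplicated(scan_key), c("participant", "timepoint", "motion")]
  scans$n_scans <- 1L
  scans$n_discarded <- as.integer(scans$motion > threshold)
  agg <- stats::aggregate(cbind(n_scans, n_discarded) ~ participant + timepoint,
                          data = scans, FUN = sum)
  agg$pct_discarded <- 100 * agg$n_discarded / agg$n_scans
  keep <- !(r$motion > threshold)
  filtered <- cluster_scan_dataset(r[keep, , drop = FALSE],
                                   timepoint_levels = levels(r$timepoint))
  list(dataset = filtered,
       report = structure(agg, threshold = threshold))
}
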