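#' Analysis configuration
#'
#' Bundles the constants of the cluster-scanning analysis: the W-score
#' threshold defining core-atrophy vertices, the W-score exclusion applied to
#' the sensorimotor control region, the motion exclusion threshold, the
#' radius of the sphere over which rigid-body displacement is summarized, and
#' the bootstrap/plateau settings of the precision analysis.
#'
#' @param w_core_threshold W-score threshold below which a vertex counts as
#'   atrophic when building the core ROI (default -2; strict `<`).
#' @param w_control_exclusion Vertices with W strictly below this value are
#'   removed from the control ROI (default -0.25).
#' @param motion_threshold Scans with RMS displacement per minute strictly
#'   above this value (mm/min) are discarded (default 10).
#' @param sphere_radius Radius in mm of the sphere used by the RMS
#'   displacement metric (default 64).
#' @param bootstrap_reps Number of bootstrap resamples (default 10000).
#' @param max_scans Number of scans resampled per timepoint for the reference
#'   atrophy rate, and the upper end of the precision curve (default 32).
#' @param plateau_rel_tol Relative improvement defining "diminishing returns"
#'   on the precision curve (default 0.05, i.e. 5% of the preceding value).
#' @param plateau_consecutive Number of consecutive qualifying steps required
#'   to declare a plateau (default 2).
#' @param alpha Family-wise significance level (default 0.05).
#' @param rng_seed Optional integer seed recorded with the configuration.
#' @return An object of class `analysis_config` (a named list).
#' @seealso [load_config()]
#' @export
analysis_config <- function(w_core_threshold = -2,
                            w_control_exclusion = -0.25,
                            motion_threshold = 10,
                            sphere_radius = 64,
                            bootstrap_reps = 10000,
                            max_scans = 32,
                            plateau_rel_tol = 0.05,
                            plateau_consecutive = 2,
                            alpha = 0.05,
                            rng_seed = NULL) {
  cs_assert(is_number(w_core_threshold), "w_core_threshold must be a finite number")
  cs_assert(is_number(w_control_exclusion), "w_control_exclusion must be a finite number")
  cs_assert(is_number(motion_threshold) && motion_threshold >= 0,
            "motion_threshold must be a finite non-negative number")
  cs_assert(is_number(sphere_radius) && sphere_radius > 0,
            "sphere_radius must be a positive number")
  cs_assert(is_count(bootstrap_reps, min = 1), "bootstrap_reps must be >= 1")
  cs_assert(is_count(max_scans, min = 1), "max_scans must be >= 1")
  cs_assert(is_number(plateau_rel_tol) && plateau_rel_tol > 0 && plateau_rel_tol < 1,
            "plateau_rel_tol must lie strictly between 0 and 1")
  cs_assert(is_count(plateau_consecutive, min = 1), "plateau_consecutive must be >= 1")
  cs_assert(is_number(alpha) && alpha > 0 && alpha < 1,
            "alpha must lie strictly between 0 and 1")
  if (!is.null(rng_seed)) {
    cs_assert(is_count(rng_seed, min = 0), "rng_seed must be a non-negative integer")
    rng_seed <- as.integer(rng_seed)
  }
  structure(
    list(
      w_core_threshold = w_core_threshold,
      w_control_exclusion = w_control_exclusion,
      motion_threshold = motion_threshold,
      sphere_radius = sphere_radius,
      bootstrap_reps = as.integer(bootstrap_reps),
      max_scans = as.integer(max_scans),
      plateau_rel_tol = plateau_rel_tol,
      plateau_consecutive = plateau_consecutive,
      alpha = alpha,
      rng_seed = rng_seed
    ),
    class = "analysis_config"
  )
}

#' Load an analysis configuration from YAML or JSON
#'
#' Unspecified keys take the defaults documented in [analysis_config()];
#' unknown keys are an error so that typos cannot silently fall back to
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   the all-defaults configuration.
#' @return An `analysis_config` object.
#' @export
load_config <- function(path) {
  cs_assert(file.exists(path), "config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  values <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(values)) values <- list()
  cs_assert(is.list(values), "config file must contain a mapping of keys to values")
  known <- setdiff(names(formals(analysis_config)), "")
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    cs_abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, values)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Cluster-scanning analysis configuration\n")
  for (k in setdiff(names(x), "rng_seed")) {
    cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  }
  if (!is.null(x$rng_seed)) cat(sprintf("  %-22s %d\n", "rng_seed", x$rng_seed))
  invisible(x)
}
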