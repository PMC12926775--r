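# Bootstrap precision analysis: how many scans per timepoint are needed
# before pooling more gives diminishing returns? The reference atrophy rate
# is the mean of B bootstrap thickness-difference estimates at 32 resampled
# scans per timepoint; the precision curve tracks the mean percent deviation
# of k-scan bootstrap estimates from that reference for k = 1..32.

#' Bootstrap reference atrophy rate
#'
#' Each bootstrap estimate is `mean(resampled reference-timepoint values) -
#' mean(resampled follow-up values)` with `n_resample` scans drawn with
#' replacement per timepoint (32 by default, even when fewer scans survived
#' QC); the reference rate is the average over `B` estimates. Positive
#' values are cortical thinning.
#'
#' @param x_ref,x_fol Per-scan ROI mean thickness (mm) at the reference and
#'   follow-up timepoints.
#' @param n_resample Scans drawn with replacement per timepoint (default 32).
#' @param B Number of bootstrap estimates (default 10000).
#' @param seed Integer seed.
#' @return Reference atrophy rate in mm.
#' @export
reference_rate <- function(x_ref, x_fol, n_resample = 32, B = 10000, seed = 1L) {
  cs_assert(length(x_ref) >= 1 && length(x_fol) >= 1,
            "need at least one scan per timepoint")
  cs_assert(is_count(B, min = 1), "B must be >= 1")
  cs_assert(is_count(n_resample, min = 1), "n_resample must be >= 1")
  set.seed(seed)
  est <- bootstrap_estimates(x_ref, x_fol, n_resample, B)
  mean(est)
}

bootstrap_estimates <- function(x_ref, x_fol, k, B) {
  ref <- matrix(sample(x_ref, B * k, replace = TRUE), B, k)
  fol <- matrix(sample(x_fol, B * k, replace = TRUE), B, k)
  rowMeans(ref) - rowMeans(fol)
}

#' Bootstrap precision curve over scans per timepoint
#'
#' For each scan count `k`, draws `B` bootstrap estimates of the thickness
#' difference using `k` scans with replacement per timepoint and measures
#' the percent deviation `100 * |estimate - reference| / reference` from the
#' bootstrap reference rate. Fresh draws are used for every `k`. Intended
#' for ROIs with a clear decline; a reference rate near zero (e.g. a control
#' ROI) makes percent deviation ill-defined and is refused.
#'
#' @inheritParams reference_rate
#' @param k_range Scan counts to evaluate (default `1:32`).
#' @param reference Optional precomputed reference rate; computed via
#'   [reference_rate()] (with `n_resample = max(k_range)`) when missing.
#' @param tol Minimum |reference| (mm) accepted (default 1e-3).
#' @param label Interval label carried into the result (e.g. `"BL - M6"`).
#' @param rel_tol,consecutive Plateau rule settings, see [detect_plateau()].
#' @return An object of class `precision_curve`: data frame with one row per
#'   `k` (`k`, `mean_deviation`, `q1`, `q3`, all in percent) plus attributes
#'   `reference_rate`, `B`, `seed`, `label`, `plateau_k` and
#'   `plateau_deviation`.
#' @export
deviation_curve <- function(x_ref, x_fol, k_range = 1:32, B = 10000,
                            seed = 1L, reference = NULL, tol = 1e-3,
                            label = "interval", rel_tol = 0.05,
                            consecutive = 2) {
  cs_assert(is_count(B, min = 1), "B must be >= 1")
  if (is.null(reference)) {
    reference <- reference_rate(x_ref, x_fol, n_resample = max(k_range),
                                B = B, seed = derive_seed(seed, 0))
  }
  if (!is.finite(reference) || abs(reference) < tol) {
    cs_abort(paste0("reference atrophy rate (%.5f mm) is below tolerance %g; ",
                    "percent deviation is ill-defined (use a declining core ROI)"),
             reference, tol)
  }
  rows <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    set.seed(derive_seed(seed, i))
    est <- bootstrap_estimates(x_ref, x_fol, k, B)
    dev <- 100 * abs(est - reference) / abs(reference)
    q <- quartiles(dev)
    data.frame(k = k, mean_deviation = mean(dev), q1 = q["q1"], q3 = q["q3"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  plateau <- if (nrow(out) >= consecutive + 1) {
    detect_plateau(out, rel_tol = rel_tol, consecutive = consecutive)
  } else {
    list(plateau_k = NA_integer_, plateau_deviation = NA_real_)
  }
  structure(out, reference_rate = reference, B = B, seed = seed,
            label = label, plateau_k = plateau$plateau_k,
            plateau_deviation = plateau$plateau_deviation,
            class = c("precision_curve", "data.frame"))
}

#' @export
print.precision_curve <- function(x, ...) {
  cat(sprintf("Precision curve [%s]: reference rate = %.4f mm, B = %d, k = %d..%d\n",
              attr(x, "label"), attr(x, "reference_rate"), attr(x, "B"),
              min(x$k), max(x$k)))
  pk <- attr(x, "plateau_k")
  if (is.na(pk)) {
    cat("  no sustained-diminishing-returns plateau detected\n")
  } else {
    cat(sprintf("  plateau at %d scans/timepoint (mean deviation %.2f%%)\n",
                pk, attr(x, "plateau_deviation")))
  }
  invisible(x)
}

#' Sustained-diminishing-returns plateau of a precision curve
#'
#' Finds the smallest scan count `K` such that, for each of the last
#' `consecutive` steps ending at `K`, the reduction in deviation is strictly
#' less than `rel_tol` times the immediately preceding deviation value.
#' Increases in deviation (negative reductions) also qualify. Returns `NA`
#' when the curve never plateaus.
#'
#' @param curve A `precision_curve` or a numeric vector of mean deviations
#'   ordered by scan count.
#' @param rel_tol Relative reduction defining diminishing returns
#'   (default 0.05 = 5% of the preceding value).
#' @param consecutive Number of consecutive qualifying steps required
#'   (default 2).
#' @return A list with `plateau_k` (scan count, `NA` if none) and
#'   `plateau_deviation` (mean percent deviation at the plateau).
#' @export
detect_plateau <- function(curve, rel_tol = 0.05, consecutive = 2) {
  tabular <- is.data.frame(curve) && all(c("k", "mean_deviation") %in% names(curve))
  dev <- if (tabular) curve$mean_deviation else as.numeric(curve)
  ks <- if (tabular) curve$k else seq_along(dev)
  cs_assert(length(dev) >= consecutive + 1,
            "curve must have length >= consecutive + 1")
  cs_assert(is_number(rel_tol) && rel_tol > 0 && rel_tol < 1,
            "rel_tol must lie strictly between 0 and 1")
  qualifies <- (dev[-length(dev)] - dev[-1]) < rel_tol * dev[-length(dev)]
  run <- 0L
  for (j in seq_along(qualifies)) {
    run <- if (qualifies[j]) run + 1L else 0L
    if (run >= consecutive) {
      return(list(plateau_k = ks[j + 1L], plateau_deviation = dev[j + 1L]))
    }
  }
  list(plateau_k = NA_integer_, plateau_deviation = NA_real_)
}

#' Extract per-scan ROI mean thickness for a timepoint
#'
#' Convenience accessor used by the precision analysis: one value per scan,
#' for the chosen ROI unit and timepoint.
#'
#' @param dataset A [cluster_scan_dataset()].
#' @param timepoint Timepoint label.
#' @param unit ROI unit name (default `"core"`).
#' @return Numeric vector of per-scan thickness (mm).
#' @export
scan_values <- function(dataset, timepoint, unit = "core") {
  r <- dataset$records
  v <- r$thickness[r$timepoint == timepoint & r$unit == unit]
  cs_assert(length(v) >= 1, "no scans for timepoint %s, unit %s", timepoint, unit)
  v
}
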