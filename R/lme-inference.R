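# Inference on a fitted atrophy model: estimated marginal means over the
# Timepoint x ROI grid (motion held at its sample mean), pairwise timepoint
# contrasts within ROI, interaction (core-minus-control) contrasts, percent
# change, and Wald F tests of the fixed terms.

emm_design_rows <- function(fit, grid) {
  grid$motion <- fit$motion_mean
  grid$timepoint <- factor(grid$timepoint, levels = fit$tp_levels)
  if (!is.null(fit$roi_levels)) {
    grid$roi <- factor(grid$roi, levels = fit$roi_levels)
  }
  stats::model.matrix(fit$mm_terms, grid, xlev = fit$xlevels)
}

emm_grid <- function(fit) {
  if (is.null(fit$roi_levels)) {
    expand.grid(timepoint = fit$tp_levels, stringsAsFactors = FALSE)
  } else {
    expand.grid(timepoint = fit$tp_levels, roi = fit$roi_levels,
                stringsAsFactors = FALSE)
  }
}

#' Estimated marginal means of the Timepoint (x ROI) grid
#'
#' Model-based cell means with the motion covariate fixed at its sample
#' mean, with Wald confidence intervals using the fit's degrees-of-freedom
#' method.
#'
#' @param fit An [fit_lme()] result.
#' @param alpha Two-sided interval level (default 0.05 for 95% CIs).
#' @return A data frame of class `emm_table` with columns `timepoint`,
#'   (`roi`,) `emm`, `se`, `df`, `lower`, `upper`.
#' @export
estimated_marginal_means <- function(fit, alpha = 0.05) {
  cs_assert(inherits(fit, "lme_fit"), "fit must be an lme_fit")
  grid <- emm_grid(fit)
  L <- emm_design_rows(fit, grid)
  emm <- as.numeric(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% fit$vcov_beta) * L))
  df <- vapply(seq_len(nrow(L)), function(i) {
    if (fit$df_method == "containment") fit$df_by_level[length(fit$df_by_level)]
    else contrast_df(fit, L[i, ])
  }, numeric(1))
  tcrit <- stats::qt(1 - alpha / 2, df)
  out <- cbind(grid, data.frame(emm = emm, se = se, df = df,
                                lower = emm - tcrit * se,
                                upper = emm + tcrit * se))
  attr(out, "alpha") <- alpha
  attr(out, "motion") <- fit$motion_mean
  class(out) <- c("emm_table", "data.frame")
  out
}

timepoint_pairs <- function(tp_levels) {
  idx <- utils::combn(seq_along(tp_levels), 2)
  data.frame(earlier = tp_levels[idx[1, ]], later = tp_levels[idx[2, ]],
             stringsAsFactors = FALSE)
}

contrast_row <- function(fit, L, label, roi, family_size, alpha) {
  delta <- sum(L * fit$beta)
  se <- sqrt(as.numeric(t(L) %*% fit$vcov_beta %*% L))
  df <- contrast_df(fit, L)
  tval <- delta / se
  p_raw <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(1 - alpha / 2, df)
  data.frame(label = label, roi = roi, delta = delta, se = se,
             lower = delta - tcrit * se, upper = delta + tcrit * se,
             t = tval, df = df, p_raw = p_raw,
             p_adjusted = pmin(1, family_size * p_raw),
             family_size = family_size, stringsAsFactors = FALSE)
}

#' Pairwise timepoint contrasts within each ROI
#'
#' For every pair of timepoints and each ROI, estimates
#' `delta = emm(earlier) - emm(later)` (coded reference-minus-later, so a
#' positive delta is cortical thinning), with Bonferroni adjustment over the
#' full family (3 timepoint pairs x 2 ROIs = 6 by default).
#'
#' @param fit An [fit_lme()] result.
#' @param alpha Interval level (default 0.05).
#' @return A data frame of class `contrast_result` with columns `label`,
#'   `roi`, `delta` (mm), `se`, `lower`, `upper` (unadjusted CI), `t`, `df`,
#'   `p_raw`, `p_adjusted` (`min(1, family_size * p_raw)`), `family_size`.
#' @export
pairwise_contrasts <- function(fit, alpha = 0.05) {
  cs_assert(inherits(fit, "lme_fit"), "fit must be an lme_fit")
  pairs <- timepoint_pairs(fit$tp_levels)
  rois <- if (is.null(fit$roi_levels)) NA_character_ else fit$roi_levels
  family_size <- nrow(pairs) * length(rois)
  rows <- list()
  for (roi in rois) {
    for (i in seq_len(nrow(pairs))) {
      g_e <- data.frame(timepoint = pairs$earlier[i])
      g_l <- data.frame(timepoint = pairs$later[i])
      if (!is.na(roi)) { g_e$roi <- roi; g_l$roi <- roi }
      L <- emm_design_rows(fit, g_e)[1, ] - emm_design_rows(fit, g_l)[1, ]
      rows[[length(rows) + 1L]] <- contrast_row(
        fit, L, sprintf("%s - %s", pairs$earlier[i], pairs$later[i]),
        roi, family_size, alpha)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Interaction contrasts: differential atrophy of core versus control
#'
#' For each timepoint pair, estimates
#' `delta = (core decline) - (control decline)`, i.e. how much more the core
#' ROI thinned than the control ROI over the interval, with Bonferroni
#' adjustment over the 3 timepoint pairs.
#'
#' @param fit An [fit_lme()] result with both ROIs in the model.
#' @param alpha Interval level (default 0.05).
#' @return A `contrast_result` data frame (one row per timepoint pair).
#' @export
interaction_contrasts <- function(fit, alpha = 0.05) {
  cs_assert(inherits(fit, "lme_fit"), "fit must be an lme_fit")
  cs_assert(!is.null(fit$roi_levels) && length(fit$roi_levels) == 2,
            "interaction contrasts need exactly two ROIs in the model")
  pairs <- timepoint_pairs(fit$tp_levels)
  family_size <- nrow(pairs)
  core <- fit$roi_levels[1]
  control <- fit$roi_levels[2]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    Lrow <- function(tp, roi) emm_design_rows(
      fit, data.frame(timepoint = tp, roi = roi))[1, ]
    L <- (Lrow(pairs$earlier[i], core) - Lrow(pairs$later[i], core)) -
      (Lrow(pairs$earlier[i], control) - Lrow(pairs$later[i], control))
    contrast_row(fit, L, sprintf("%s - %s", pairs$earlier[i], pairs$later[i]),
                 sprintf("%s vs %s", core, control), family_size, alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Percent change between two timepoints
#'
#' `100 * (emm(later) - emm(reference)) / emm(reference)`, so cortical
#' thinning is negative. Report tables round to one decimal.
#'
#' @param emms An [estimated_marginal_means()] table.
#' @param pair Character vector `c(reference, later)` of timepoint labels.
#' @param roi ROI name (omit for single-unit tables).
#' @param digits Rounding for the returned value; `NULL` for unrounded.
#' @return Percent change (negative = thinning).
#' @export
percent_change <- function(emms, pair, roi = NULL, digits = 1) {
  cs_assert(inherits(emms, "emm_table") || is.data.frame(emms),
            "emms must be an emm_table")
  cs_assert(length(pair) == 2, "pair must be c(reference, later)")
  pick <- function(tp) {
    rows <- emms$timepoint == tp
    if (!is.null(roi) && "roi" %in% names(emms)) rows <- rows & emms$roi == roi
    v <- emms$emm[rows]
    cs_assert(length(v) == 1, "cell (%s%s) not found or not unique", tp,
              if (is.null(roi)) "" else paste0(", ", roi))
    v
  }
  ref <- pick(pair[1])
  later <- pick(pair[2])
  cs_assert(ref > 0, "reference estimated marginal mean must be positive")
  pc <- 100 * (later - ref) / ref
  if (is.null(digits)) pc else round(pc, digits)
}

#' Bonferroni-adjusted per-test threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param family_size Number of comparisons in the family.
#' @param digits Optional rounding (e.g. 3 reproduces the conventional
#'   printed thresholds .008 for a family of 6 and .017 for a family of 3).
#' @return `alpha / family_size`, optionally rounded.
#' @export
bonferroni_threshold <- function(alpha = 0.05, family_size, digits = NULL) {
  cs_assert(is_count(family_size, min = 1), "family_size must be a positive count")
  th <- alpha / family_size
  if (is.null(digits)) th else round(th, digits)
}

#' Wald F tests of the fixed-effect terms
#'
#' Marginal (default) tests use the Wald statistic
#' `F = b' V_b^{-1} b / q` for each term's coefficients given all others;
#' sequential tests add terms in model order on the whitened
#' (GLS-decorrelated) design. Denominator degrees of freedom follow the
#' fit's df method.
#'
#' @param fit An [fit_lme()] result.
#' @param type `"marginal"` or `"sequential"`.
#' @return A data frame with `term`, `df_num`, `df_den`, `F`, `p`.
#' @export
anova_fixed_effects <- function(fit, type = c("marginal", "sequential")) {
  cs_assert(inherits(fit, "lme_fit"), "fit must be an lme_fit")
  type <- match.arg(type)
  terms <- fit$term_labels
  rows <- vector("list", length(terms))
  if (type == "marginal") {
    for (ti in seq_along(terms)) {
      idx <- which(fit$assign == ti)
      q <- length(idx)
      b <- fit$beta[idx]
      Fval <- as.numeric(t(b) %*% solve(fit$vcov_beta[idx, idx, drop = FALSE]) %*% b) / q
      Lref <- rep(0, length(fit$beta)); Lref[idx] <- 1
      dfd <- contrast_df(fit, Lref)
      rows[[ti]] <- data.frame(term = terms[ti], df_num = q, df_den = dfd,
                               F = Fval,
                               p = stats::pf(Fval, q, dfd, lower.tail = FALSE))
    }
  } else {
    yt <- fit$whitened$yt
    Xt <- fit$whitened$Xt
    rss_prev <- sum(qr.resid(qr(Xt[, fit$assign == 0, drop = FALSE]), yt)^2)
    for (ti in seq_along(terms)) {
      cols <- which(fit$assign <= ti)
      rss <- sum(qr.resid(qr(Xt[, cols, drop = FALSE]), yt)^2)
      q <- sum(fit$assign == ti)
      Fval <- ((rss_prev - rss) / q) / fit$sigma2
      Lref <- rep(0, length(fit$beta)); Lref[fit$assign == ti] <- 1
      dfd <- contrast_df(fit, Lref)
      rows[[ti]] <- data.frame(term = terms[ti], df_num = q, df_den = dfd,
                               F = Fval,
                               p = stats::pf(Fval, q, dfd, lower.tail = FALSE))
      rss_prev <- rss
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
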