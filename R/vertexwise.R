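# Vertex-wise mixed models inside the core mask. Each vertex is modeled with
# Timepoint + motion fixed effects (no ROI factor: the analysis runs inside
# one mask) through a singular-fit fallback cascade: nested random
# intercepts -> scan-only -> fixed-effects-only.

#' Fit one vertex with the singular-fit fallback cascade
#'
#' Tries the nested day/session/scan random-intercept model first; on a
#' singular fit (any variance component at the boundary) refits with scan
#' random intercepts only; if that is singular too, falls back to a
#' fixed-effects-only model. The cascade is deterministic given the data.
#'
#' @param vertex_data Data frame with columns `timepoint`, `day`, `session`,
#'   `scan`, `motion`, `thickness` (one row per scan).
#' @param timepoint_levels Ordering of timepoints.
#' @param df_method Degrees-of-freedom method passed to the engine.
#' @param control [lme_control()] list.
#' @return A list with `fit` (an `lme_fit`, or `NULL` when all three models
#'   fail to converge) and `model_code` (2 = nested, 1 = scan-only,
#'   0 = fixed-only, `NA` = missing).
#' @export
fit_vertex_cascade <- function(vertex_data, timepoint_levels = NULL,
                               df_method = "containment",
                               control = lme_control()) {
  needed <- c("timepoint", "day", "session", "scan", "motion", "thickness")
  cs_assert(all(needed %in% names(vertex_data)),
            "vertex_data needs columns: %s", paste(needed, collapse = ", "))
  if (is.null(timepoint_levels)) {
    timepoint_levels <- unique(as.character(vertex_data$timepoint))
  }
  r <- data.frame(timepoint = factor(as.character(vertex_data$timepoint),
                                     levels = timepoint_levels),
                  day = vertex_data$day, session = vertex_data$session,
                  scan = vertex_data$scan, motion = vertex_data$motion,
                  thickness = vertex_data$thickness, unit = "vertex",
                  stringsAsFactors = FALSE)
  dat <- prepare_model_frame(r)
  cascade <- list(c(random = "nested", code = 2),
                  c(random = "scan", code = 1),
                  c(random = "none", code = 0))
  for (step in cascade) {
    fit <- tryCatch(
      fit_lme_frame(dat, random = step[["random"]], strata = "none",
                    df_method = df_method, control = control),
      lme_nonconvergence = function(e) NULL,
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!fit$singular || step[["random"]] == "none") {
      return(list(fit = fit, model_code = as.integer(step[["code"]])))
    }
  }
  list(fit = NULL, model_code = NA_integer_)
}

#' Vertex-wise percent-change maps with the dual-threshold significance rule
#'
#' Fits the fallback cascade at every vertex of a mask, computes percent
#' change between timepoints from vertex-wise estimated marginal means, and
#' flags a vertex-pair as significant when the Timepoint main effect has
#' `p < alpha` and the pairwise contrast has `p < alpha / 3`
#' (Bonferroni over the three timepoint pairs; at the default
#' `alpha = 0.05` the per-pair threshold prints as .017). No further
#' vertex-level multiplicity adjustment is applied. Vertices where the whole
#' cascade fails are propagated as explicit `NA` rows, never zero-filled.
#'
#' @param thickness Scans x vertices matrix of thickness (mm); column order
#'   defines vertex order.
#' @param scans Data frame of per-scan covariates (`timepoint`, `day`,
#'   `session`, `scan`, `motion`), rows aligned with `thickness`.
#' @param mask Optional [roi_mask()] restricting which vertices (0-based,
#'   matching column positions) are fitted; default all columns.
#' @param timepoint_levels Ordering of timepoints.
#' @param alpha Main-effect significance level (default 0.05).
#' @param df_method,control Passed to the per-vertex engine.
#' @return A data frame of class `vertex_change_map` with one row per vertex
#'   x timepoint pair: `vertex` (0-based), `pair`, `percent_change`,
#'   `p_main`, `p_pair`, `significant`, `model_code`.
#' @export
vertex_change_maps <- function(thickness, scans, mask = NULL,
                               timepoint_levels = NULL, alpha = 0.05,
                               df_method = "containment",
                               control = lme_control()) {
  thickness <- as.matrix(thickness)
  cs_assert(nrow(thickness) == nrow(scans),
            "thickness rows must align with the scans table")
  if (is.null(timepoint_levels)) {
    timepoint_levels <- unique(as.character(scans$timepoint))
  }
  vertices <- if (is.null(mask)) seq_len(ncol(thickness)) - 1L else mask$vertices
  cs_assert(all(vertices >= 0 & vertices < ncol(thickness)),
            "mask vertices outside the thickness matrix")
  pair_thresh <- alpha / 3
  rows <- list()
  for (v in vertices) {
    vd <- cbind(scans, thickness = thickness[, v + 1L])
    res <- fit_vertex_cascade(vd, timepoint_levels = timepoint_levels,
                              df_method = df_method, control = control)
    pairs <- timepoint_pairs(timepoint_levels)
    if (is.null(res$fit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        vertex = v, pair = sprintf("%s - %s", pairs$earlier, pairs$later),
        percent_change = NA_real_, p_main = NA_real_, p_pair = NA_real_,
        significant = NA, model_code = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    emms <- estimated_marginal_means(res$fit, alpha = alpha)
    ctr <- pairwise_contrasts(res$fit, alpha = alpha)
    p_main <- anova_fixed_effects(res$fit)$p[1]
    pc <- vapply(seq_len(nrow(pairs)), function(i) {
      percent_change(emms, c(pairs$earlier[i], pairs$later[i]), digits = NULL)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      vertex = v, pair = ctr$label, percent_change = pc,
      p_main = p_main, p_pair = ctr$p_raw,
      significant = p_main < alpha & ctr$p_raw < pair_thresh,
      model_code = res$model_code, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vertex_change_map", "data.frame")
  out
}
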