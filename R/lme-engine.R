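# Restricted maximum likelihood engine for the participant-level atrophy
# model: Timepoint x ROI fixed effects plus a motion covariate, nested
# random intercepts for scans within sessions within days, and residual
# variances stratified by ROI (or ROI x Timepoint). The marginal covariance
# is V = sum_l sigma2_l Z_l Z_l' + sigma2 * diag(w_stratum^2); the engine
# optimizes the restricted log-likelihood over log relative variances
# gamma_l = sigma2_l / sigma2 and log stratum weights with sigma2 profiled
# out, then reports GLS fixed effects at the optimum.

#' Control parameters for the REML optimizer
#'
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @param restarts Number of jittered restarts before declaring
#'   non-convergence.
#' @param singular_tol Relative variance below which a component counts as
#'   being on the boundary (fit flagged singular).
#' @return A named list.
#' @export
lme_control <- function(maxit = 1000, reltol = 1e-10, restarts = 3,
                        singular_tol = 1e-6) {
  list(maxit = maxit, reltol = reltol, restarts = restarts,
       singular_tol = singular_tol)
}

# Core REML computation on a prepared design.
# y: response; X: fixed design; group_list: named list of grouping factors,
# outermost first; stratum: factor for residual weight strata or NULL;
# theta: optional list(gamma=, weights=) fixing the variance parameters.
reml_engine <- function(y, X, group_list, stratum = NULL, theta = NULL,
                        control = lme_control()) {
  n <- length(y)
  p <- ncol(X)
  cs_assert(all(is.finite(y)), "response contains non-finite values")
  cs_assert(n > p, "need more observations (%d) than fixed effects (%d)", n, p)
  ng <- length(group_list)
  group_idx <- lapply(group_list, function(g) as.integer(factor(g)))
  if (!is.null(stratum)) {
    stratum <- factor(stratum)
    if (nlevels(stratum) < 2) stratum <- NULL
  }
  # A grouping factor whose groups are all singletons is confounded with the
  # residual (an exact likelihood ridge when the residual is unweighted);
  # its variance is fixed at the most parsimonious point of the ridge, zero,
  # and marked aliased rather than estimated.
  aliased <- vapply(group_idx, function(gi)
    is.null(stratum) && max(gi) == n, logical(1))
  est_idx <- which(!aliased)
  masks <- lapply(group_idx[est_idx], function(gi) 1 * outer(gi, gi, "=="))
  ng_est <- length(est_idx)
  ns <- if (is.null(stratum)) 1L else nlevels(stratum)
  si <- if (is.null(stratum)) rep(1L, n) else as.integer(stratum)
  npar <- ng_est + (ns - 1L)

  eval_at <- function(par) {
    gam <- if (ng_est > 0) exp(pmin(par[seq_len(ng_est)], 25)) else numeric(0)
    w <- if (ns > 1) c(1, exp(pmin(par[ng_est + seq_len(ns - 1L)], 25))) else 1
    V0 <- diag((w^2)[si], n)
    for (l in seq_len(ng_est)) V0 <- V0 + gam[l] * masks[[l]]
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Q <- backsolve(R, cbind(y, X), transpose = TRUE)
    yt <- Q[, 1]
    Xt <- Q[, -1, drop = FALSE]
    qrX <- qr(Xt)
    if (qrX$rank < p) return(NULL)
    beta <- qr.coef(qrX, yt)
    rss <- sum(qr.resid(qrX, yt)^2)
    sigma2 <- max(rss / (n - p), 1e-300)
    ldet_v0 <- 2 * sum(log(diag(R)))
    ldet_xvx <- 2 * sum(log(abs(diag(qr.R(qrX)))))
    neg_reml <- 0.5 * ((n - p) * (log(2 * pi) + log(sigma2) + 1) +
                         ldet_v0 + ldet_xvx)
    list(neg_reml = neg_reml, beta = beta, sigma2 = sigma2, gam = gam, w = w,
         qrX = qrX, R = R, yt = yt, Xt = Xt)
  }
  objective <- function(par) {
    res <- eval_at(par)
    if (is.null(res) || !is.finite(res$neg_reml)) 1e12 else res$neg_reml
  }

  start_par <- function(jitter = 0) {
    e <- qr.resid(qr(X), y)
    s_all <- stats::sd(e)
    if (!is.finite(s_all) || s_all <= 0) s_all <- 1
    lw <- if (ns > 1) {
      s_strat <- vapply(seq_len(ns), function(s) {
        v <- stats::sd(e[si == s])
        if (!is.finite(v) || v <= 0) s_all else v
      }, numeric(1))
      log(s_strat[-1] / s_strat[1])
    } else numeric(0)
    c(rep(log(0.3), ng_est), lw) + stats::rnorm(npar, 0, jitter)
  }

  trace <- list()
  if (!is.null(theta)) {
    gam <- if (ng > 0) theta$gamma else numeric(0)
    cs_assert(length(gam) == ng, "theta$gamma must match the random structure")
    w_extra <- if (ns > 1) theta$weights[-1] / theta$weights[1] else numeric(0)
    par <- c(log(pmax(gam[est_idx], 1e-300)), log(w_extra))
    opt <- list(par = par, convergence = 0L, value = objective(par), fixed = TRUE)
  } else if (npar == 0L) {
    opt <- list(par = numeric(0), convergence = 0L, value = objective(numeric(0)))
  } else {
    run_from <- function(par0) {
      # PORT local search, then a Nelder-Mead polish to step over ridges
      cand <- tryCatch(
        stats::nlminb(par0, objective, lower = rep(-30, npar),
                      upper = rep(15, npar),
                      control = list(iter.max = control$maxit)),
        error = function(e) NULL)
      par1 <- if (is.null(cand)) par0 else cand$par
      pol <- if (npar == 1L) {
        stats::optim(par1, objective, method = "Brent", lower = -30, upper = 15)
      } else {
        stats::optim(par1, objective, method = "Nelder-Mead",
                     control = list(maxit = control$maxit,
                                    reltol = control$reltol))
      }
      if (!is.null(cand) && cand$objective < pol$value) {
        list(par = cand$par, value = cand$objective, convergence = 0L)
      } else {
        list(par = pol$par, value = pol$value, convergence = pol$convergence)
      }
    }
    opt <- NULL
    for (attempt in 0:control$restarts) {
      cand <- run_from(start_par(jitter = 0.6 * attempt))
      trace[[length(trace) + 1L]] <- c(convergence = cand$convergence,
                                       value = cand$value)
      ok <- cand$convergence == 0 && is.finite(cand$value) && cand$value < 1e11
      if (ok && (is.null(opt) || cand$value < opt$value - 1e-8)) opt <- cand
      if (!is.null(opt) && attempt >= 1) break
      if (!is.null(opt) && attempt == 0) break
    }
    if (is.null(opt)) {
      cond <- structure(
        class = c("lme_nonconvergence", "error", "condition"),
        list(message = sprintf("REML optimizer failed to converge after %d restarts",
                               control$restarts),
             call = sys.call(-1), trace = trace))
      stop(cond)
    }
  }

  final <- eval_at(opt$par)
  cs_assert(!is.null(final), "REML solution is numerically degenerate")
  xvx_inv <- chol2inv(qr.R(final$qrX))
  vcov_beta <- final$sigma2 * xvx_inv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- final$beta
  names(beta) <- colnames(X)
  gam <- numeric(ng)
  gam[est_idx] <- final$gam
  names(gam) <- names(group_list)
  names(aliased) <- names(group_list)
  weights <- final$w
  if (ns > 1) names(weights) <- levels(stratum)
  singular <- (ng_est > 0 && any(final$gam < control$singular_tol)) ||
    (ng > 0 && ng_est == 0)
  list(beta = beta, vcov_beta = vcov_beta, sigma2 = final$sigma2,
       gamma = gam, varcomp = gam * final$sigma2, weights = weights,
       aliased = aliased,
       logLik = -opt$value, n_obs = n, p = p,
       converged = TRUE, singular = singular,
       whitened = list(yt = final$yt, Xt = final$Xt),
       stratum = stratum, optim_trace = trace)
}

# Innermost-constancy level of each fixed-effect column for containment
# degrees of freedom: a column is assigned to the outermost grouping level
# within whose groups it is constant; columns varying within every group sit
# at the observation level. The intercept is assigned level 0.
containment_levels <- function(X, group_list) {
  ng <- length(group_list)
  lv <- integer(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (all(x == x[1])) { lv[j] <- 0L; next }
    lv[j] <- ng + 1L
    for (l in seq_len(ng)) {
      rngs <- tapply(x, group_list[[l]], function(v) diff(range(v)))
      if (all(rngs < 1e-10)) { lv[j] <- l; break }
    }
  }
  lv
}

containment_df <- function(X, group_list, n) {
  ng <- length(group_list)
  lv <- containment_levels(X, group_list)
  m <- c(1L, vapply(group_list, function(g) length(unique(g)), integer(1)), n)
  p_at <- tabulate(lv, nbins = ng + 1L)
  df <- m[-1] - m[-length(m)] - p_at
  list(levels = lv, df_by_level = pmax(df, 1L))
}

#' Fit the longitudinal atrophy mixed model to a cluster-scan dataset
#'
#' Fits, by restricted maximum likelihood, cortical thickness on Timepoint,
#' ROI, their interaction, and the per-scan motion score (a covariate of no
#' interest), with nested random intercepts for scans within sessions within
#' days and residual variances stratified by ROI across timepoints. The
#' reference levels are the first timepoint and the `core` ROI (or the first
#' ROI present). When the dataset holds a single unit (e.g. one vertex), the
#' fixed part reduces to Timepoint + motion.
#'
#' @param dataset A [cluster_scan_dataset()] (after motion QC).
#' @param random Random-intercept structure: `"nested"`
#'   (day/session/scan, the default), `"scan"` (scans only), or `"none"`.
#' @param strata Residual variance strata: `"roi_timepoint"` (default, one
#'   weight per ROI x Timepoint cell), `"roi"`, `"timepoint"`, or `"none"`.
#' @param df_method Denominator degrees of freedom: `"containment"`
#'   (default, a between-within heuristic over the grouping hierarchy),
#'   `"residual"` (`n - p`), or `"normal"` (infinite df, z tests).
#' @param theta Optional list `list(gamma = , weights = )` fixing the
#'   relative variance components and stratum weights (no optimization);
#'   mainly for oracle checks and warm starts.
#' @param control A [lme_control()] list.
#' @return An object of class `lme_fit`: fixed effects and covariance,
#'   variance components (`varcomp`), residual `sigma2` and stratum
#'   `weights`, restricted log-likelihood, convergence/singularity flags,
#'   and the design metadata needed by [estimated_marginal_means()],
#'   [pairwise_contrasts()], [interaction_contrasts()] and
#'   [anova_fixed_effects()].
#' @export
fit_lme <- function(dataset, random = c("nested", "scan", "none"),
                    strata = c("roi_timepoint", "roi", "timepoint", "none"),
                    df_method = c("containment", "residual", "normal"),
                    theta = NULL, control = lme_control()) {
  cs_assert(inherits(dataset, "cluster_scan_dataset"),
            "dataset must be a cluster_scan_dataset")
  random <- match.arg(random)
  strata <- match.arg(strata)
  df_method <- match.arg(df_method)
  r <- dataset$records[dataset$records$unit_type == "roi", , drop = FALSE]
  cs_assert(nrow(r) > 0, "dataset has no ROI-level records")
  dat <- prepare_model_frame(r)
  fit_lme_frame(dat, random = random, strata = strata, df_method = df_method,
                theta = theta, control = control)
}

prepare_model_frame <- function(r, unit_col = "unit") {
  cs_assert(!anyNA(r$motion), "motion scores must be complete for the mixed model")
  tp <- droplevels(r$timepoint)
  cs_assert(nlevels(tp) >= 2, "the mixed model needs >= 2 timepoints")
  units <- unique(r[[unit_col]])
  roi <- NULL
  if (length(units) > 1) {
    ref <- if ("core" %in% units) "core" else units[1]
    roi <- factor(r[[unit_col]], levels = c(ref, setdiff(units, ref)))
  }
  day_g <- interaction(tp, r$day, drop = TRUE)
  session_g <- interaction(day_g, r$session, drop = TRUE)
  scan_g <- interaction(session_g, r$scan, drop = TRUE)
  out <- data.frame(thickness = r$thickness, timepoint = tp,
                    motion = r$motion, day_g = day_g, session_g = session_g,
                    scan_g = scan_g)
  if (!is.null(roi)) out$roi <- roi
  out
}

fit_lme_frame <- function(dat, random, strata, df_method, theta = NULL,
                          control = lme_control()) {
  use_roi <- "roi" %in% names(dat)
  fixed <- if (use_roi) thickness ~ timepoint * roi + motion
           else thickness ~ timepoint + motion
  X <- stats::model.matrix(fixed, dat)
  y <- dat$thickness
  group_list <- switch(random,
    nested = list(day = dat$day_g, session = dat$session_g, scan = dat$scan_g),
    scan = list(scan = dat$scan_g),
    none = list())
  stratum <- switch(strata,
    roi_timepoint = if (use_roi) interaction(dat$roi, dat$timepoint, drop = TRUE) else NULL,
    roi = if (use_roi) dat$roi else NULL,
    timepoint = dat$timepoint,
    none = NULL)
  eng <- reml_engine(y, X, group_list, stratum = stratum, theta = theta,
                     control = control)
  cdf <- containment_df(X, group_list, length(y))
  fit <- c(eng, list(
    random = random, strata = strata, df_method = df_method,
    fixed = fixed, assign = attr(X, "assign"),
    term_labels = attr(stats::terms(fixed), "term.labels"),
    mm_terms = stats::delete.response(stats::terms(fixed)),
    xlevels = stats::.getXlevels(stats::terms(fixed), dat),
    motion_mean = mean(dat$motion),
    tp_levels = levels(dat$timepoint),
    roi_levels = if (use_roi) levels(dat$roi) else NULL,
    col_levels = cdf$levels, df_by_level = cdf$df_by_level,
    fingerprint = c(n = length(y), sum = sum(y), ss = sum(y^2))
  ))
  class(fit) <- "lme_fit"
  fit
}

#' @export
print.lme_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed-effects fit (REML), %d observations\n", x$n_obs))
  cat(sprintf("  random: %s | residual strata: %s | logLik(REML) = %.3f\n",
              x$random, x$strata, x$logLik))
  if (length(x$varcomp) > 0) {
    cat("  variance components (SD, mm):",
        paste(sprintf("%s = %.4g", names(x$varcomp), sqrt(x$varcomp)),
              collapse = ", "), "\n")
  }
  cat(sprintf("  residual SD = %.4g mm", sqrt(x$sigma2)))
  if (length(x$weights) > 1) {
    cat("; stratum weights:",
        paste(sprintf("%s = %.3g", names(x$weights), x$weights), collapse = ", "))
  }
  cat("\n")
  if (x$singular) cat("  note: singular fit (variance component at boundary)\n")
  print(round(x$beta, digits))
  invisible(x)
}

# df for a linear combination of fixed effects under the containment rule:
# innermost level among the columns the combination touches.
contrast_df <- function(fit, L) {
  if (fit$df_method == "normal") return(Inf)
  if (fit$df_method == "residual") return(fit$n_obs - fit$p)
  active <- which(abs(L) > 1e-12 & fit$col_levels > 0)
  lev <- if (length(active) == 0) length(fit$df_by_level) else max(fit$col_levels[active])
  if (lev == 0) lev <- length(fit$df_by_level)
  fit$df_by_level[lev]
}

#' Likelihood-ratio test between random-effect structures
#'
#' Compares the nested day/session/scan random-intercept model with the
#' simpler scans-only model on the same data and fixed effects:
#' `statistic = 2 * (logLik_full - logLik_simple)` (clipped at zero),
#' referred to a chi-squared distribution with 2 degrees of freedom. The
#' simpler model is retained when `p > alpha`. The REML likelihoods are
#' comparable because the fixed-effect specification is identical; the
#' boundary-null conservatism of the plain chi-squared reference is accepted
#' as the conventional choice.
#'
#' @param full An `lme_fit` with `random = "nested"`.
#' @param simple An `lme_fit` with `random = "scan"` on the same data.
#' @param alpha Retention threshold (default 0.05).
#' @return A list with `statistic`, `df`, `p_value`, and `retain`
#'   (`"scan"` when the simpler model suffices, else `"nested"`).
#' @export
lrt_random_structure <- function(full, simple, alpha = 0.05) {
  cs_assert(inherits(full, "lme_fit") && inherits(simple, "lme_fit"),
            "both arguments must be lme_fit objects")
  cs_assert(full$random == "nested" && simple$random == "scan",
            "expected a nested full model and a scan-only simple model")
  cs_assert(identical(names(full$beta), names(simple$beta)),
            "models must share the same fixed effects")
  if (max(abs(full$fingerprint - simple$fingerprint)) > 1e-8) {
    cs_abort("models were fitted to different data (fingerprint mismatch)")
  }
  stat <- max(0, 2 * (full$logLik - simple$logLik))
  df <- 2
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p,
       retain = if (p > alpha) "scan" else "nested")
}
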