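test_that("noise-free balanced data reproduce the cell means exactly", {
  truth <- synthetic_truth(sigma_day = 0, sigma_session = 0, sigma_scan = 0,
                           resid_sd = c(core = 1e-4, control = 1e-4),
                           motion_effect = 0)
  sim <- generate_cluster_dataset(truth, design = c(3, 1, 1, 6), seed = 2)
  fit <- fit_lme(sim$dataset, random = "nested", strata = "none")
  emms <- estimated_marginal_means(fit)
  for (i in seq_len(nrow(emms))) {
    expect_equal(emms$emm[i],
                 truth$cell_means[as.character(emms$timepoint[i]),
                                  as.character(emms$roi[i])],
                 tolerance = 1e-3)
  }
  expect_true(fit$singular)
  expect_lt(max(fit$varcomp), 1e-6)
})

test_that("REML on balanced one-way data equals the closed-form ANOVA estimators", {
  # g groups x m replicates, intercept-only fixed part: REML variance
  # components have the classical ANOVA closed form
  set.seed(71)
  g <- 12; m <- 4
  for (rep in 1:3) {
    grp <- rep(seq_len(g), each = m)
    y <- 2 + rnorm(g, 0, 0.3)[grp] + rnorm(g * m, 0, 0.5)
    records <- data.frame(participant = "p", timepoint = rep(c("A", "B"), g * m / 2),
                          stringsAsFactors = FALSE)
    # build through the low-level engine: intercept-only design
    eng <- clusterscan:::reml_engine(
      y, matrix(1, g * m, 1, dimnames = list(NULL, "(Intercept)")),
      group_list = list(scan = factor(grp)), stratum = NULL)
    gm <- tapply(y, grp, mean)
    ms_between <- m * sum((gm - mean(y))^2) / (g - 1)
    ms_within <- sum((y - gm[grp])^2) / (g * (m - 1))
    expect_equal(eng$sigma2, ms_within, tolerance = 1e-6)
    expect_equal(unname(eng$varcomp["scan"]), (ms_between - ms_within) / m,
                 tolerance = 1e-6)
    expect_equal(unname(eng$beta), mean(y), tolerance = 1e-8)
  }
})

test_that("fixed effects equal the GLS closed form when variance components are known", {
  truth <- synthetic_truth()
  sim <- generate_cluster_dataset(truth, design = c(3, 2, 2, 3), seed = 33)
  gamma <- c(day = 0.3, session = 0.2, scan = 0.8)
  weights <- c(1, 1.4, 0.9, 1.2, 1.1, 1.6)
  fit <- fit_lme(sim$dataset, theta = list(gamma = gamma, weights = weights))
  # direct GLS oracle from the marginal covariance
  r <- sim$dataset$records
  dat <- data.frame(timepoint = r$timepoint,
                    roi = factor(r$unit, levels = c("core", "control")),
                    motion = r$motion)
  X <- model.matrix(~ timepoint * roi + motion, dat)
  n <- nrow(X)
  fac <- list(day = interaction(r$timepoint, r$day, drop = TRUE),
              session = interaction(r$timepoint, r$day, r$session, drop = TRUE),
              scan = interaction(r$timepoint, r$day, r$session, r$scan, drop = TRUE))
  stratum <- interaction(factor(r$unit, levels = c("core", "control")),
                         r$timepoint, drop = TRUE)
  V <- diag((weights^2)[as.integer(stratum)], n)
  for (l in seq_along(fac)) {
    Z <- outer(fac[[l]], fac[[l]], "==") * 1
    V <- V + gamma[l] * Z
  }
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, r$thickness))
  expect_equal(unname(fit$beta), as.numeric(beta_gls), tolerance = 1e-8)
})

test_that("the fit agrees with the reference mixed-model implementation", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("emmeans")
  sim <- generate_cluster_dataset(seed = 7)
  fit <- fit_lme(sim$dataset)
  r <- sim$dataset$records
  dat <- data.frame(thickness = r$thickness, timepoint = r$timepoint,
                    roi = factor(r$unit, levels = c("core", "control")),
                    motion = r$motion,
                    day = interaction(r$timepoint, r$day, drop = TRUE),
                    session = interaction(r$timepoint, r$day, r$session, drop = TRUE),
                    scan = interaction(r$timepoint, r$day, r$session, r$scan, drop = TRUE))
  dat$stratum <- interaction(dat$roi, dat$timepoint)
  m <- nlme::lme(thickness ~ timepoint * roi + motion, data = dat,
                 random = ~ 1 | day/session/scan,
                 weights = nlme::varIdent(form = ~ 1 | stratum),
                 method = "REML")
  expect_equal(fit$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_equal(unname(fit$beta), unname(nlme::fixef(m)), tolerance = 1e-5)
  expect_equal(sqrt(fit$sigma2), m$sigma, tolerance = 1e-3)

  em <- as.data.frame(emmeans::emmeans(m, ~ timepoint * roi))
  emms <- estimated_marginal_means(fit)
  ord <- order(as.character(emms$roi), as.character(emms$timepoint))
  ord_em <- order(as.character(em$roi), as.character(em$timepoint))
  expect_equal(emms$emm[ord], em$emmean[ord_em], tolerance = 1e-5)
  expect_equal(emms$se[ord], em$SE[ord_em], tolerance = 1e-4)

  prs <- as.data.frame(emmeans::contrast(emmeans::emmeans(m, ~ timepoint | roi),
                                         "pairwise", adjust = "none"))
  ctr <- pairwise_contrasts(fit)
  ord_c <- order(as.character(ctr$roi), as.character(ctr$label))
  ord_p <- order(as.character(prs$roi), as.character(prs$contrast))
  expect_equal(ctr$delta[ord_c], prs$estimate[ord_p], tolerance = 1e-6)
  expect_equal(ctr$se[ord_c], prs$SE[ord_p], tolerance = 1e-4)

  # sequential F tests match the reference implementation's anova table
  ft <- anova_fixed_effects(fit, type = "sequential")
  ref <- stats::anova(m)
  expect_equal(ft$F, ref$`F-value`[-1], tolerance = 1e-3)
  expect_equal(ft$df_den, ref$denDF[-1])
})

test_that("EMMs shift equivariantly and contrast deltas are definitional", {
  sim <- generate_cluster_dataset(seed = 19)
  fit <- fit_lme(sim$dataset, random = "scan")
  emms <- estimated_marginal_means(fit)
  shifted <- sim$dataset
  shifted$records$thickness <- shifted$records$thickness + 0.5
  fit_s <- fit_lme(shifted, random = "scan")
  emms_s <- estimated_marginal_means(fit_s)
  expect_equal(emms_s$emm, emms$emm + 0.5, tolerance = 1e-6)

  ctr <- pairwise_contrasts(fit)
  for (i in seq_len(nrow(ctr))) {
    tp <- strsplit(ctr$label[i], " - ")[[1]]
    e1 <- emms$emm[emms$timepoint == tp[1] & emms$roi == ctr$roi[i]]
    e2 <- emms$emm[emms$timepoint == tp[2] & emms$roi == ctr$roi[i]]
    expect_equal(ctr$delta[i], e1 - e2, tolerance = 1e-12)
  }
  ictr <- interaction_contrasts(fit)
  core_d <- ctr$delta[ctr$roi == "core"]
  ctl_d <- ctr$delta[ctr$roi == "control"]
  expect_equal(ictr$delta, core_d - ctl_d, tolerance = 1e-12)
  expect_equal(ictr$family_size, rep(3, 3))
  expect_true(all(ctr$family_size == 6))
  # Bonferroni adjustment: p_adjusted = min(1, family * p_raw), order-invariant
  expect_equal(ctr$p_adjusted, pmin(1, 6 * ctr$p_raw))
  perm <- sample(nrow(ctr))
  expect_equal(ctr$p_adjusted[perm], pmin(1, 6 * ctr$p_raw[perm]))
})

test_that("percent change divides by the reference-timepoint mean", {
  sim <- generate_cluster_dataset(seed = 23)
  fit <- fit_lme(sim$dataset, random = "scan")
  emms <- estimated_marginal_means(fit)
  e <- function(tp) emms$emm[emms$timepoint == tp & emms$roi == "core"]
  expect_equal(percent_change(emms, c("BL", "M6"), "core", digits = NULL),
               100 * (e("M6") - e("BL")) / e("BL"))
  expect_equal(percent_change(emms, c("BL", "BL"), "core"), 0)
  fake <- emms
  fake$emm[fake$timepoint == "BL" & fake$roi == "core"] <- -1
  expect_error(percent_change(fake, c("BL", "M6"), "core"), "positive")
})

test_that("fixed-effect F tests carry the design degrees of freedom", {
  sim <- generate_cluster_dataset(seed = 29)
  fit <- fit_lme(sim$dataset, random = "scan")
  ft <- anova_fixed_effects(fit)
  expect_equal(ft$term, c("timepoint", "roi", "motion", "timepoint:roi"))
  expect_equal(ft$df_num, c(2, 1, 1, 2))
  # containment denominators for the scan-only model: between-scan terms get
  # n_scans - 1 - 3, within-scan terms n_obs - n_scans - 3
  expect_equal(ft$df_den, c(92, 93, 92, 93))
})

test_that("the likelihood-ratio test selects the generating random structure", {
  # identical log-likelihoods: statistic 0, simple retained
  sim <- generate_cluster_dataset(seed = 41)
  full <- fit_lme(sim$dataset, random = "nested")
  simple <- fit_lme(sim$dataset, random = "scan")
  fake_full <- full
  fake_full$logLik <- simple$logLik
  res0 <- lrt_random_structure(fake_full, simple)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$retain, "scan")

  # under the null (no day/session variance) the simple model is retained
  null_truth <- synthetic_truth(sigma_day = 0, sigma_session = 0)
  n_null <- 24
  retained <- vapply(seq_len(n_null), function(i) {
    ds <- generate_cluster_dataset(null_truth, seed = derive_seed(600, i))$dataset
    lrt_random_structure(fit_lme(ds, random = "nested"),
                         fit_lme(ds, random = "scan"))$retain
  }, character(1))
  expect_gte(mean(retained == "scan"), 0.85)

  # under a strong day effect the full model is retained
  alt_truth <- synthetic_truth(sigma_day = 0.05)
  retained_alt <- vapply(1:10, function(i) {
    ds <- generate_cluster_dataset(alt_truth, seed = derive_seed(700, i))$dataset
    lrt_random_structure(fit_lme(ds, random = "nested"),
                         fit_lme(ds, random = "scan"))$retain
  }, character(1))
  expect_gte(mean(retained_alt == "nested"), 0.9)

  other <- generate_cluster_dataset(seed = 43)$dataset
  expect_error(lrt_random_structure(fit_lme(other, random = "nested"), simple),
               "fingerprint")
})

test_that("the REML optimum is at least as good as the generating parameters", {
  truth <- synthetic_truth()
  for (s in 1:4) {
    sim <- generate_cluster_dataset(truth, design = c(3, 2, 2, 4),
                                    seed = derive_seed(800, s))
    fit <- fit_lme(sim$dataset)
    sigma2_core <- truth$resid_sd[["core"]]^2
    gamma_truth <- c(day = truth$sigma_day^2, session = truth$sigma_session^2,
                     scan = truth$sigma_scan^2) / sigma2_core
    w_truth <- rep(c(1, truth$resid_sd[["control"]] / truth$resid_sd[["core"]]),
                   3)
    at_truth <- fit_lme(sim$dataset,
                        theta = list(gamma = gamma_truth, weights = w_truth))
    expect_gte(fit$logLik, at_truth$logLik - 1e-6)
  }
})
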