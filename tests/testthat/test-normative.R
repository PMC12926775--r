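test_that("an exactly interpolating cohort is fit exactly and flagged degenerate", {
  cohort <- list(age = c(60, 70, 60, 70), sex = c(0, 0, 1, 1),
                 thickness = matrix(c(2.0, 1.9, 2.1, 2.0), 4, 1))
  m <- fit_normative(cohort)
  expect_equal(m$beta0, 2.6)
  expect_equal(m$beta1, -0.01)
  expect_equal(m$beta2, 0.1)
  expect_true(m$degenerate)
  expect_error(compute_wscores(m, 65, 1, 2.0), "degenerate")
  expect_warning(w <- compute_wscores(m, 65, 1, 2.0, on_degenerate = "na"),
                 "degenerate")
  expect_true(is.na(w$w))
})

test_that("coefficients equal the normal-equations solution on random cohorts", {
  for (s in 1:5) {
    co <- generate_normative_cohort(n = 10, n_male = 5, resid_sd = 0.2,
                                    n_units = 3, seed = s)
    m <- fit_normative(co)
    X <- cbind(1, co$age, co$sex)
    oracle <- solve(crossprod(X), crossprod(X, co$thickness))
    expect_equal(rbind(m$beta0, m$beta1, m$beta2), unname(oracle),
                 tolerance = 1e-10)
    oracle_sd <- sqrt(colSums((co$thickness - X %*% oracle)^2) / (10 - 3))
    expect_equal(m$resid_sd, unname(oracle_sd), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  cohort <- list(age = rep(65, 6), sex = rep(1, 6),
                 thickness = matrix(rnorm(6, 2), 6, 1))
  expect_error(fit_normative(cohort), "rank deficient")
  same_age <- list(age = rep(65, 6), sex = rep(c(0, 1), 3),
                   thickness = matrix(rnorm(6, 2), 6, 1))
  expect_error(fit_normative(same_age), "age")
  expect_error(fit_normative(list(age = c(60, 61, 62), sex = c(0, 1, 0),
                                  thickness = matrix(rnorm(3, 2), 3, 1))),
               ">= 4 subjects")
})

test_that("W-scores compute the covariate-adjusted deviation", {
  co <- generate_normative_cohort(n = 30, n_male = 14, resid_sd = 0.1,
                                  n_units = 2, seed = 8)
  m <- fit_normative(co)
  pred <- m$beta0 + m$beta1 * 72 + m$beta2 * 1
  w <- compute_wscores(m, 72, 1, pred)
  expect_equal(w$w, c(0, 0))

  m1 <- structure(list(beta0 = 2.6, beta1 = -0.01, beta2 = 0.1,
                       resid_sd = 0.05, degenerate = FALSE, n_subjects = 25,
                       sd_denom = "df", units = "roi"),
                  class = "normative_model")
  w1 <- compute_wscores(m1, 77, 1, 1.83)
  expect_equal(w1$predicted, 1.93)
  expect_equal(w1$w, -2)

  m2 <- structure(list(beta0 = 2.0, beta1 = 0, beta2 = 0, resid_sd = 0.1,
                       degenerate = FALSE, n_subjects = 25, sd_denom = "df",
                       units = "roi"),
                  class = "normative_model")
  expect_equal(compute_wscores(m2, 70, 0, 1.8)$w, -2)
})

test_that("training-cohort W-scores are mean zero per unit", {
  co <- generate_normative_cohort(n = 40, n_male = 18, resid_sd = 0.15,
                                  n_units = 5, seed = 12)
  m <- fit_normative(co)
  ws <- sapply(seq_len(40), function(i) {
    compute_wscores(m, co$age[i], co$sex[i], co$thickness[i, ])$w
  })
  expect_lt(max(abs(rowMeans(ws))), 1e-10)
})

test_that("W-scores are invariant to centering the age covariate", {
  co <- generate_normative_cohort(n = 25, n_male = 13, resid_sd = 0.1,
                                  n_units = 2, seed = 15)
  m <- fit_normative(co)
  centered <- co
  centered$age <- co$age - mean(co$age)
  mc <- fit_normative(centered)
  subj_age <- 71
  w_raw <- compute_wscores(m, subj_age, 1, c(1.9, 2.0))$w
  w_cen <- compute_wscores(mc, subj_age - mean(co$age), 1, c(1.9, 2.0))$w
  expect_equal(w_raw, w_cen, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(m$beta0, mc$beta0)))
})

test_that("estimated residual SD is consistent as the cohort grows", {
  co <- generate_normative_cohort(n = 1000, n_male = 500, resid_sd = 0.1,
                                  n_units = 1, seed = 20)
  m <- fit_normative(co)
  expect_equal(m$resid_sd, 0.1, tolerance = 0.05)
})

test_that("normative models survive a JSON round trip", {
  co <- generate_normative_cohort(n = 12, n_male = 6, resid_sd = 0.1,
                                  n_units = 3, seed = 9)
  m <- fit_normative(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_json(m, path)
  back <- read_normative_json(path)
  for (f in c("beta0", "beta1", "beta2", "resid_sd")) {
    expect_equal(back[[f]], m[[f]], tolerance = 1e-12)
  }
  expect_equal(back$n_subjects, m$n_subjects)
})
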