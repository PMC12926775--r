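# W-score normative modeling: per-unit ordinary least squares of cortical
# thickness on age and sex in a control cohort, then conversion of observed
# thickness to W-scores (residuals in units of the control residual SD).
# More negative W means thinner cortex than expected for age and sex.

#' Fit the per-unit normative age/sex regression
#'
#' For each unit (vertex or ROI), fits `thickness = beta0 + beta1 * age +
#' beta2 * sex + e` by ordinary least squares on the control cohort. The
#' residual SD per unit defaults to the unbiased `sqrt(RSS / (n - 3))`
#' (residual degrees of freedom); `sd_denom = "n-1"` is available for
#' pipelines that used the plain sample SD of the residuals.
#'
#' @param cohort A [generate_normative_cohort()] result, or any list with
#'   numeric `age`, binary `sex` (0 = female, 1 = male) and a subjects x
#'   units `thickness` matrix.
#' @param sd_denom `"df"` (default, `n - 3`) or `"n-1"`.
#' @param degenerate_tol Units with residual SD below this are flagged
#'   degenerate (default 1e-8).
#' @return An object of class `normative_model`: per-unit `beta0`, `beta1`,
#'   `beta2`, `resid_sd`, `degenerate` flag, plus `n_subjects`, `sd_denom`
#'   and `units` names.
#' @export
fit_normative <- function(cohort, sd_denom = c("df", "n-1"),
                          degenerate_tol = 1e-8) {
  sd_denom <- match.arg(sd_denom)
  age <- as.numeric(cohort$age)
  sex <- as.numeric(cohort$sex)
  Y <- as.matrix(cohort$thickness)
  n <- length(age)
  cs_assert(length(sex) == n && nrow(Y) == n,
            "age, sex and thickness must agree on the number of subjects")
  cs_assert(all(sex %in% c(0, 1)), "sex must be coded 0 (female) / 1 (male)")
  cs_assert(n >= 4, "the normative regression needs >= 4 subjects (3 parameters)")
  X <- cbind(`(Intercept)` = 1, age = age, sex = sex)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    cs_abort("normative design matrix is rank deficient; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, Y)
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, 3, 1)
  res <- as.matrix(fit$residuals)
  denom <- if (sd_denom == "df") n - 3 else n - 1
  resid_sd <- sqrt(colSums(res^2) / denom)
  units <- colnames(Y)
  if (is.null(units)) units <- sprintf("unit%04d", seq_len(ncol(Y)) - 1L)
  structure(list(beta0 = unname(coefs[1, ]), beta1 = unname(coefs[2, ]),
                 beta2 = unname(coefs[3, ]), resid_sd = unname(resid_sd),
                 degenerate = unname(resid_sd < degenerate_tol),
                 n_subjects = n, sd_denom = sd_denom, units = units),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model: %d unit(s), %d subjects (resid SD denominator: %s)\n",
              length(x$beta0), x$n_subjects,
              if (x$sd_denom == "df") "n - 3" else "n - 1"))
  if (any(x$degenerate)) {
    cat(sprintf("  %d degenerate unit(s) (zero residual variance)\n",
                sum(x$degenerate)))
  }
  invisible(x)
}

#' Convert observed thickness to W-scores
#'
#' `W = (observed - predicted) / resid_sd`, with
#' `predicted = beta0 + beta1 * age + beta2 * sex` from the normative model.
#' W is a covariate-adjusted z-like score; values near 0 are typical for the
#' subject's age and sex, and negative values indicate thinner cortex.
#'
#' @param model A [fit_normative()] result.
#' @param age Subject age in years.
#' @param sex Subject sex code (0 = female, 1 = male).
#' @param thickness Observed thickness per unit (mm), in model unit order.
#' @param on_degenerate `"error"` (default) to refuse degenerate units, or
#'   `"na"` to return `NA` W-scores there with a warning.
#' @return An object of class `wscore_map`: list with `w`, `predicted`,
#'   `observed` and `units`.
#' @export
compute_wscores <- function(model, age, sex, thickness,
                            on_degenerate = c("error", "na")) {
  cs_assert(inherits(model, "normative_model"), "model must be a normative_model")
  on_degenerate <- match.arg(on_degenerate)
  cs_assert(is_number(age), "age must be a single number")
  cs_assert(sex %in% c(0, 1), "sex must be coded 0 (female) / 1 (male)")
  thickness <- as.numeric(thickness)
  cs_assert(length(thickness) == length(model$beta0),
            "thickness must provide one value per model unit (%d)", length(model$beta0))
  predicted <- model$beta0 + model$beta1 * age + model$beta2 * sex
  w <- (thickness - predicted) / model$resid_sd
  if (any(model$degenerate)) {
    if (on_degenerate == "error") {
      cs_abort("%d unit(s) have degenerate (zero) residual SD; refit or use on_degenerate = 'na'",
               sum(model$degenerate))
    }
    w[model$degenerate] <- NA_real_
    warning(sprintf("%d degenerate unit(s) set to NA", sum(model$degenerate)),
            call. = FALSE)
  }
  structure(list(w = w, predicted = predicted, observed = thickness,
                 units = model$units),
            class = "wscore_map")
}

#' @export
print.wscore_map <- function(x, ...) {
  cat(sprintf("W-score map: %d unit(s); median W = %.2f, %d unit(s) with W < -2\n",
              length(x$w), stats::median(x$w, na.rm = TRUE),
              sum(x$w < -2, na.rm = TRUE)))
  invisible(x)
}

#' Serialize / restore a normative model as JSON
#'
#' @param model A `normative_model`.
#' @param path Output path.
#' @return For `read_normative_json`, a `normative_model`.
#' @export
write_normative_json <- function(model, path) {
  cs_assert(inherits(model, "normative_model"), "model must be a normative_model")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative_json
#' @export
read_normative_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$degenerate <- as.logical(obj$degenerate)
  structure(obj, class = "normative_model")
}
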