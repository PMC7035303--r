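#' Specify a multivariable association model
#'
#' One GLM of the association analysis: an outcome, its family/link (fixed
#' by the outcome: gamma with log link for the right-skewed WMH burden,
#' Gaussian with identity link for TBV and cognition), the basic covariate
#' set (age, sex, MAP, hypertension, tCBF), one pulsatility term entered at
#' a time (ICA or M1, PI or FVP; M3 is not used in multivariable analysis),
#' optional extra adjustments, and an optional restriction to the SVD
#' subgroup.
#'
#' @param outcome `"wmh_pct_icv"`, `"tbv_pct_icv"` or `"cognition"`.
#' @param pulsatility_term One of `"ICA_PI"`, `"M1_PI"`, `"ICA_FVP"`,
#'   `"M1_FVP"`, `"none"`.
#' @param extra_adjustments Character subset of `"antihypertensives"` (four
#'   drug-class indicators) and `"wmh_tbv"` (WMH volume and TBV, used for
#'   the cognition model).
#' @param subgroup `"all"` or `"svd_only"`.
#' @param base_covariates Ordered covariate set; the default is the basic
#'   model (age, sex, MAP, hypertension, tCBF). `character()` gives an
#'   intercept-only fit (plus the pulsatility term, if any).
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome = c("wmh_pct_icv", "tbv_pct_icv", "cognition"),
                       pulsatility_term = c("ICA_PI", "M1_PI", "ICA_FVP",
                                            "M1_FVP", "none"),
                       extra_adjustments = character(),
                       subgroup = c("all", "svd_only"),
                       base_covariates = c("age", "sex_female", "map",
                                           "hypertension", "tcbf")) {
  outcome <- match.arg(outcome)
  pulsatility_term <- match.arg(pulsatility_term)
  subgroup <- match.arg(subgroup)
  bad <- setdiff(extra_adjustments, c("antihypertensives", "wmh_tbv"))
  if (length(bad)) stopf("unknown extra adjustments: %s",
                         paste(bad, collapse = ", "))
  if (outcome == "wmh_pct_icv" && "wmh_tbv" %in% extra_adjustments) {
    stopf("cannot adjust the WMH model for WMH itself")
  }
  family_link <- if (outcome == "wmh_pct_icv") "gamma_log" else "gaussian_identity"
  structure(list(outcome = outcome, family_link = family_link,
                 base_covariates = base_covariates,
                 pulsatility_term = pulsatility_term,
                 extra_adjustments = extra_adjustments,
                 subgroup = subgroup),
            class = "model_spec")
}

## Map spec term labels to cohort columns (R-R-standardized, bilateral).
term_column <- c(ICA_PI = "ica_pi", M1_PI = "m1_pi",
                 ICA_FVP = "ica_fvp", M1_FVP = "m1_fvp")

outcome_column <- c(wmh_pct_icv = "wmh_pct_icv", tbv_pct_icv = "tbv_pct_icv",
                    cognition = "aggregate_z")

#' Fit one association GLM
#'
#' Fits the model described by a [model_spec] on a cohort table by
#' iteratively reweighted least squares (relative deviance convergence
#' `1e-8`, at most 100 iterations), with complete-case deletion of rows
#' missing any model variable. Confidence intervals are Wald intervals on
#' the coefficient scale (`estimate +/- 1.96 SE`) and dispersion is
#' estimated from the Pearson statistic, `X^2 / (n - p)`; p-values are
#' Wald normal-approximation tests. Gamma/log models require a strictly
#' positive outcome.
#'
#' @param spec A [model_spec].
#' @param cohort Cohort `data.frame` (as from [generate_cohort()] or
#'   [read_cohort_csv()]); `sex_female` is derived from a `sex` column if
#'   absent.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A `fit_result`: list with `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `ci_lower`, `ci_upper`, `p`), `dispersion`,
#'   `n_used`, `converged`, `iterations`, and the originating `spec`.
#'   Non-convergence is flagged, not an error.
#' @export
fit_glm <- function(spec, cohort, conf_level = 0.95) {
  stopifnot(inherits(spec, "model_spec"))
  cohort <- as.data.frame(cohort)
  if (!"sex_female" %in% names(cohort) && "sex" %in% names(cohort)) {
    cohort$sex_female <- as.integer(cohort$sex == "F")
  }
  ycol <- outcome_column[[spec$outcome]]
  covars <- spec$base_covariates
  if ("antihypertensives" %in% spec$extra_adjustments) {
    covars <- c(covars, "beta_blocker", "raas", "ccb", "diuretic")
  }
  if ("wmh_tbv" %in% spec$extra_adjustments) {
    covars <- c(covars, "wmh_pct_icv", "tbv_pct_icv")
  }
  if (spec$pulsatility_term != "none") {
    covars <- c(covars, term_column[[spec$pulsatility_term]])
  }
  need <- c(ycol, covars, if (spec$subgroup == "svd_only") "svd")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort is missing model variables: %s",
                          paste(miss, collapse = ", "))
  d <- cohort[, need, drop = FALSE]
  if (spec$subgroup == "svd_only") {
    d <- d[as.logical(d$svd) %in% TRUE, setdiff(names(d), "svd"), drop = FALSE]
  }
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) {
    stopf("only %d complete cases; at least 10 required", nrow(d))
  }
  if (spec$family_link == "gamma_log" && any(d[[ycol]] <= 0)) {
    stopf("gamma/log outcome must be strictly positive")
  }
  fml <- stats::as.formula(paste(ycol, "~",
                                 if (length(covars)) paste(covars, collapse = " + ")
                                 else "1"))
  ## guard against rank deficiency before IRLS
  X <- stats::model.matrix(fml, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(aliased, collapse = ", "))
  }
  fam <- if (spec$family_link == "gamma_log") Gamma(link = "log") else gaussian()
  fit <- stats::glm(fml, data = d, family = fam,
                    control = glm.control(epsilon = 1e-8, maxit = 100))
  p <- length(coef(fit))
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / (fit$df.residual)
  sm <- summary(fit, dispersion = dispersion)
  est <- sm$coefficients[, 1]
  se <- sm$coefficients[, 2]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = rownames(sm$coefficients), estimate = est,
                      se = se, ci_lower = est - zq * se,
                      ci_upper = est + zq * se,
                      p = 2 * pnorm(-abs(est / se)),
                      row.names = NULL)
  structure(list(coefficients = coefs, dispersion = dispersion,
                 n_used = nrow(d), converged = fit$converged,
                 iterations = fit$iter, spec = spec,
                 family_link = spec$family_link),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s), n = %d, %s in %d iterations\n",
              x$spec$outcome, x$family_link, x$n_used,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$coefficients, digits = 4)
  invisible(x)
}

## The pulsatility-term row of a fit, as a one-row summary data.frame.
battery_row <- function(fit, variant) {
  spec <- fit$spec
  term <- if (spec$pulsatility_term == "none") NA_character_ else
    term_column[[spec$pulsatility_term]]
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  data.frame(outcome = spec$outcome, pulsatility_term = spec$pulsatility_term,
             variant = variant, subgroup = spec$subgroup,
             estimate = row$estimate, ci_lower = row$ci_lower,
             ci_upper = row$ci_upper, p = row$p, n = fit$n_used,
             converged = fit$converged)
}

#' Run the full model battery
#'
#' Runs, with pulsatility terms entered one at a time:
#' * the basic model (age, sex, MAP, hypertension, tCBF) for each of
#'   ICA-PI, M1-PI, ICA-FVP, M1-FVP against WMH volume, TBV and cognition
#'   (12 fits);
#' * extended models: WMH and TBV additionally adjusted for the four
#'   antihypertensive drug classes; cognition additionally adjusted for WMH
#'   volume and TBV;
#' * the SVD-subgroup basic models for WMH and TBV (cognition is excluded
#'   in the subgroup: too few follow-ups).
#'
#' A subgroup (or extended) model with fewer than 10 complete cases is
#' skipped with a warning; the full-sample results are still returned.
#'
#' @param cohort Cohort `data.frame`.
#' @param terms Pulsatility terms to enter (default all four).
#' @return A `model_battery` object: list with `results` (tidy
#'   `data.frame`, one row per fitted model) and `fits` (named list of
#'   `fit_result`s).
#' @export
run_model_battery <- function(cohort,
                              terms = c("ICA_PI", "M1_PI", "ICA_FVP",
                                        "M1_FVP")) {
  fits <- list()
  rows <- list()
  try_fit <- function(spec, variant) {
    key <- paste(spec$outcome, spec$pulsatility_term, variant, spec$subgroup,
                 sep = ".")
    res <- tryCatch(fit_glm(spec, cohort), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("model %s skipped: %s", key, conditionMessage(res)),
              call. = FALSE)
      return(invisible(NULL))
    }
    fits[[key]] <<- res
    rows[[key]] <<- battery_row(res, variant)
    invisible(NULL)
  }
  outcomes <- c("wmh_pct_icv", "tbv_pct_icv", "cognition")
  for (term in terms) {
    for (oc in outcomes) {
      try_fit(model_spec(oc, term), "basic")
    }
    try_fit(model_spec("wmh_pct_icv", term, "antihypertensives"), "antihypertensives")
    try_fit(model_spec("tbv_pct_icv", term, "antihypertensives"), "antihypertensives")
    try_fit(model_spec("cognition", term, "wmh_tbv"), "wmh_tbv")
    try_fit(model_spec("wmh_pct_icv", term, subgroup = "svd_only"), "basic")
    try_fit(model_spec("tbv_pct_icv", term, subgroup = "svd_only"), "basic")
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, fits = fits), class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat(sprintf("<model_battery> %d fitted models\n", nrow(x$results)))
  print(x$results, digits = 3)
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, single rater, absolute agreement:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))` with `k = 2`
#' raters, where MSR, MSC and MSE are the subject, rater and residual mean
#' squares of the two-way ANOVA.
#'
#' @param ratings_a,ratings_b Numeric rating vectors of equal length
#'   (>= 3), one element per subject.
#' @return ICC(2,1) in (-1, 1]. Errors if the ratings carry no variance.
#' @examples
#' icc_2_1(c(0, 2, 4, 6), c(0, 2, 4, 6))  # 1
#' @export
icc_2_1 <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stopf("rating vectors must have equal length")
  }
  n <- length(ratings_a)
  if (n < 3) stopf("at least 3 rated subjects required")
  x <- cbind(as.numeric(ratings_a), as.numeric(ratings_b))
  if (any(!is.finite(x))) stopf("ratings must be finite")
  k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-12) {
    stopf("ICC undefined: ratings have zero total variance")
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
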