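## Fixed 12-row table for linear-algebra oracle checks.
fixture12 <- local({
  set.seed(333)
  d <- data.frame(age = round(rnorm(12, 70, 8), 1),
                  sex_female = rep(c(0, 1), 6),
                  map = round(rnorm(12, 100, 10), 1),
                  hypertension = rep(c(1, 1, 0), 4),
                  tcbf = round(rnorm(12, 600, 90), 1))
  d$tbv_pct_icv <- 68 - 0.3 * d$age + 4 * d$sex_female + 0.1 * d$map +
    0.02 * d$tcbf + rnorm(12, 0, 2)
  d$wmh_pct_icv <- rgamma(12, 2, 2)
  d$svd <- TRUE
  d
})

test_that("gaussian identity fit equals the normal-equations solution", {
  f <- fit_glm(model_spec("tbv_pct_icv", "none"), fixture12)
  X <- cbind(1, as.matrix(fixture12[, c("age", "sex_female", "map",
                                        "hypertension", "tcbf")]))
  beta <- solve(crossprod(X), crossprod(X, fixture12$tbv_pct_icv))
  expect_equal(f$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  expect_true(f$converged)
  expect_equal(f$n_used, 12)
})

test_that("intercept-only gamma/log fit returns log of the outcome mean", {
  f <- fit_glm(model_spec("wmh_pct_icv", "none",
                          base_covariates = character()), fixture12)
  expect_equal(f$coefficients$estimate[1], log(mean(fixture12$wmh_pct_icv)),
               tolerance = 1e-8)
})

test_that("IRLS gaussian fits reproduce OLS on random full-rank designs", {
  set.seed(91)
  for (k in 1:10) {
    n <- sample(30:80, 1)
    d <- data.frame(age = rnorm(n, 70, 9), sex_female = rbinom(n, 1, 0.4),
                    map = rnorm(n, 100, 12), hypertension = rbinom(n, 1, 0.8),
                    tcbf = rnorm(n, 600, 100))
    d$tbv_pct_icv <- 60 + rnorm(n, 0, 5)
    f <- fit_glm(model_spec("tbv_pct_icv", "none"), d)
    ols <- lm(tbv_pct_icv ~ age + sex_female + map + hypertension + tcbf,
              data = d)
    expect_equal(f$coefficients$estimate, unname(coef(ols)),
                 tolerance = 1e-10)
  }
})

test_that("gamma/log fits are invariant to outcome rescaling up to intercept", {
  co <- test_cohort()
  f1 <- fit_glm(model_spec("wmh_pct_icv", "ICA_FVP"), co)
  co2 <- co
  co2$wmh_pct_icv <- co2$wmh_pct_icv * 37
  f2 <- fit_glm(model_spec("wmh_pct_icv", "ICA_FVP"), co2)
  slopes <- f1$coefficients$term != "(Intercept)"
  expect_equal(f2$coefficients$estimate[slopes],
               f1$coefficients$estimate[slopes], tolerance = 1e-8)
  expect_equal(f2$coefficients$estimate[1] - f1$coefficients$estimate[1],
               log(37), tolerance = 1e-8)
})

test_that("complete-case deletion and validation errors behave as specified", {
  co <- head(test_cohort(), 300)
  miss <- is.na(co$ica_fvp) | is.na(co$wmh_pct_icv)
  f <- fit_glm(model_spec("wmh_pct_icv", "ICA_FVP"), co)
  expect_equal(f$n_used, 300 - sum(miss))
  expect_true(all(f$coefficients$ci_lower <= f$coefficients$estimate &
                    f$coefficients$estimate <= f$coefficients$ci_upper))
  ## non-positive gamma outcome
  bad <- co
  bad$wmh_pct_icv[2] <- 0
  expect_error(fit_glm(model_spec("wmh_pct_icv", "ICA_FVP"), bad),
               "strictly positive")
  ## rank-deficient design names the collinear column
  dup <- co
  dup$tcbf <- dup$map  # duplicate column content
  dup$map <- 2 * dup$tcbf
  expect_error(fit_glm(model_spec("wmh_pct_icv", "none"), dup),
               "rank deficient.*tcbf")
  ## fewer than 10 complete cases
  expect_error(fit_glm(model_spec("wmh_pct_icv", "none"), head(co, 5)),
               "complete cases")
})

test_that("model battery runs basic, extended and subgroup variants", {
  co <- test_cohort()
  bat <- run_model_battery(co)
  res <- bat$results
  expect_equal(sum(res$variant == "basic" & res$subgroup == "all"), 12)
  expect_equal(sum(res$variant == "antihypertensives"), 8)
  expect_equal(sum(res$variant == "wmh_tbv"), 4)
  ## subgroup: WMH and TBV only, cognition excluded
  sub <- res[res$subgroup == "svd_only", ]
  expect_equal(nrow(sub), 8)
  expect_false("cognition" %in% sub$outcome)
  expect_true(all(sub$n <= sum(co$svd)))
  ## no-SVD cohort: subgroup models skipped with a warning, rest intact
  co0 <- co
  co0$svd <- FALSE
  ws <- capture_warnings(bat0 <- run_model_battery(co0))
  expect_true(all(grepl("skipped", ws)) && length(ws) == 8)
  expect_equal(sum(bat0$results$subgroup == "svd_only"), 0)
  expect_equal(sum(bat0$results$variant == "basic"), 12)
})

test_that("ICC(2,1) matches perfect agreement and the ANOVA oracle", {
  expect_equal(icc_2_1(c(0, 2, 4, 6), c(0, 2, 4, 6)), 1)
  ## reversed ratings on a symmetric vector, against the brute-force oracle
  a <- c(0, 1, 2, 3, 4, 5, 6)
  b <- rev(a)
  expect_equal(icc_2_1(a, b), icc_oracle(a, b), tolerance = 1e-12)
  ## random ordinal fixtures
  set.seed(14)
  for (k in 1:20) {
    x <- sample(0:6, 25, replace = TRUE)
    y <- pmin(6, pmax(0, x + sample(-2:2, 25, replace = TRUE)))
    if (var(c(x, y)) == 0) next
    expect_equal(icc_2_1(x, y), icc_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(icc_2_1(rep(3, 10), rep(3, 10)), "zero total variance")
  expect_error(icc_2_1(1:5, 1:4), "equal length")
})

test_that("simulated rater pairs reach the analytic ICC of their model", {
  set.seed(9)
  lat <- rnorm(500, 3, 1.2)
  rp <- simulate_rater_pair(lat, rater_sd = 0.5, rater_bias = 0, seed = 21)
  ## variance components: subject 1.2^2, rater noise 0.5^2 plus rounding
  ## quantization ~1/12
  analytic <- 1.2^2 / (1.2^2 + 0.5^2 + 1 / 12)
  expect_equal(icc_2_1(rp$rater_a, rp$rater_b), analytic, tolerance = 0.05)
})

test_that("type-I error of the pulsatility test is near nominal", {
  ## null cohorts (generative pulsatility coefficient 0): Wald p < 0.05
  ## should occur at close to the nominal 5% rate
  null_wmh <- list(intercept = -3.0, age = 0.06, sex = 0, map = 0,
                   hypertension = 0.83, tcbf = -0.006, pulsatility = 0,
                   pulsatility_term = "ica_fvp", shape = 1.2)
  rej <- vapply(1:150, function(r) {
    co <- generate_cohort(cohort_params(n_subjects = 1000, seed = 70000 + r,
                                        wmh_model = null_wmh))
    f <- fit_glm(model_spec("wmh_pct_icv", "ICA_FVP"), co)
    f$coefficients$p[f$coefficients$term == "ica_fvp"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})
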