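test_that("volume fraction arithmetic matches its definitions", {
  v <- compute_volume_fractions(600, 500, 400, 15)
  expect_equal(v$icv, 1500)
  expect_equal(v$tbv_pct_icv, 100 * 1100 / 1500)
  expect_equal(v$wmh_pct_icv, 1.0)
  expect_equal(compute_volume_fractions(600, 500, 400, 0)$wmh_pct_icv, 0)
  expect_equal(compute_volume_fractions(600, 500, 0, 1)$tbv_pct_icv, 100)
  expect_error(compute_volume_fractions(0, 0, 0, 0), "positive")
  expect_error(compute_volume_fractions(-1, 500, 400, 0), "non-negative")
})

test_that("SVD composite matches the rule on an exhaustive truth table", {
  grid <- expand.grid(fazekas = 0:6, lacune = c(FALSE, TRUE),
                      infarct = c(FALSE, TRUE), mb = 0:4)
  got <- classify_svd(grid$fazekas, grid$infarct, grid$lacune, grid$mb)
  want <- grid$fazekas >= 4 | grid$infarct | grid$lacune | grid$mb > 2
  expect_identical(got, want)
  ## the three boundary cases spelled out
  expect_true(classify_svd(4, FALSE, FALSE, 0))
  expect_false(classify_svd(3, FALSE, FALSE, 2))
  expect_true(classify_svd(0, FALSE, TRUE, 0))
  expect_error(classify_svd(NA, FALSE, FALSE, 0), "missing")
})

test_that("cognitive aggregate sums oriented Z-scores", {
  nm <- cognitive_norms()
  at_norm <- setNames(nm$mean, nm$test)
  expect_equal(aggregate_cognition(at_norm), 0)
  ## one timed test 1 SD faster than norm: aggregate +1
  better <- at_norm
  better["trail_making_a"] <- nm$mean[nm$test == "trail_making_a"] -
    nm$sd[nm$test == "trail_making_a"]
  expect_equal(aggregate_cognition(better), 1)
  ## random battery against a hand computation
  set.seed(8)
  sc <- setNames(nm$mean + rnorm(8) * nm$sd, nm$test)
  hand <- sum(nm$orientation * (sc[nm$test] - nm$mean) / nm$sd)
  expect_equal(aggregate_cognition(sc), hand)
  ## missing-subtest policy
  part <- sc[-3]
  expect_true(is.na(aggregate_cognition(part)))
  hand_part <- sum(nm$orientation[-3] * (part - nm$mean[-3]) / nm$sd[-3])
  expect_equal(aggregate_cognition(part, missing_policy = "available"),
               hand_part)
})

test_that("generated cohorts are deterministic and satisfy record invariants", {
  cp <- cohort_params(n_subjects = 1000, seed = 202)
  co <- generate_cohort(cp)
  expect_identical(co, generate_cohort(cp))
  expect_equal(nrow(co), 1000)
  ok <- !is.na(co$tbv_pct_icv)  # volumes missing iff the outcome is missing
  expect_equal(co$icv[ok], (co$gm + co$wm + co$csf)[ok])
  expect_equal(co$tbv_pct_icv[ok], (100 * (co$gm + co$wm) / co$icv)[ok])
  expect_equal(co$fazekas_total, co$fazekas_pv + co$fazekas_dwm)
  expect_true(all(co$fazekas_pv %in% 0:3 & co$fazekas_dwm %in% 0:3))
  expect_true(all(co$wmh_pct_icv > 0, na.rm = TRUE))
  expect_true(all(co$map >= pmin(co$dbp, co$sbp) &
                    co$map <= pmax(co$dbp, co$sbp)))
  expect_true(all(co$microbleed_count >= 0))
  ## bilateral fallback: averaged metric missing iff both sides missing
  for (b in c("ica_pi", "m1_fvp")) {
    both_na <- is.na(co[[paste0(b, "_left")]]) & is.na(co[[paste0(b, "_right")]])
    expect_identical(is.na(co[[b]]), both_na)
    one <- is.na(co[[paste0(b, "_left")]]) & !both_na
    expect_equal(co[[b]][one], co[[paste0(b, "_right")]][one])
  }
  ## cognition only for the follow-up fraction
  expect_equal(mean(!is.na(co$aggregate_z)), 0.539, tolerance = 0.05)
  ## subtest scores reproduce the stored aggregate through the norms
  nm <- cognitive_norms()
  i <- which(!is.na(co$aggregate_z))[1]
  sc <- setNames(as.numeric(co[i, nm$test]), nm$test)
  expect_equal(aggregate_cognition(sc), co$aggregate_z[i], tolerance = 1e-8)
})

test_that("all-zero coefficients with zero noise collapse outcomes to the mean", {
  cp <- cohort_params(
    n_subjects = 40, seed = 5,
    tbv_model = list(intercept = 66, age = 0, sex = 0, map = 0,
                     hypertension = 0, tcbf = 0, pulsatility = 0,
                     pulsatility_term = "ica_fvp", sd = 1e-12))
  co <- generate_cohort(cp)
  expect_equal(co$tbv_pct_icv, rep(66, 40), tolerance = 1e-9)
})

test_that("SVD prevalence is calibrated to the cohort-typical band", {
  co <- generate_cohort(cohort_params(n_subjects = 5000, seed = 31))
  expect_gt(mean(co$svd), 0.41)
  expect_lt(mean(co$svd), 0.51)
})

test_that("generative pulsatility effect is recovered from a large cohort", {
  ## moment check: gamma/log fit on n = 5000 recovers the generative
  ## ICA-FVP coefficient within Monte-Carlo error
  co <- generate_cohort(cohort_params(n_subjects = 5000, seed = 61))
  f <- fit_glm(model_spec("wmh_pct_icv", "ICA_FVP"), co)
  row <- f$coefficients[f$coefficients$term == "ica_fvp", ]
  expect_lt(abs(row$estimate - 1.67), 3 * row$se)
})

test_that("rater pair simulation is seeded and respects its noise model", {
  lat <- seq(0, 6, length.out = 40)
  same <- simulate_rater_pair(lat, rater_sd = 0, rater_bias = 0, seed = 4)
  expect_identical(same$rater_a, same$rater_b)
  r1 <- simulate_rater_pair(lat, 0.5, 0.2, seed = 10)
  expect_identical(r1, simulate_rater_pair(lat, 0.5, 0.2, seed = 10))
  expect_true(all(r1$rater_a %in% 0:6 & r1$rater_b %in% 0:6))
  expect_error(simulate_rater_pair(lat, -1), "rater_sd")
})
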