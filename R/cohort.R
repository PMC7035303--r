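#' Parameters of the synthetic stroke/TIA cohort
#'
#' Generative settings for [generate_cohort()]. Defaults emulate a cohort
#' of 89 acute ischemic stroke / TIA patients: covariate distributions and
#' risk-factor prevalences at cohort-typical values, segment-wise
#' pulsatility metric means and SDs (ICA/M1/M3 PI and FVP), a gamma/log
#' generative model for white matter hyperintensity burden (% of
#' intracranial volume), Gaussian/identity models for total brain volume
#' (%ICV) and the cognitive Z-aggregate, and roughly half participation in
#' the 1-year cognitive follow-up.
#'
#' The headline generative coefficients default to the magnitudes the
#' association analysis is designed to detect: ICA-FVP on log-WMH 1.67,
#' M1-PI on cognition -4.4, and no pulsatility effect on TBV.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param missing_rate Probability that a paired-artery measurement is
#'   missing on one side (applied independently per side and segment).
#' @param followup_rate Fraction of subjects with cognitive follow-up.
#' @param wmh_model,tbv_model,cognition_model Named lists of generative
#'   coefficients (`intercept`, `age`, `sex`, `map`, `hypertension`,
#'   `tcbf`, `pulsatility`, plus `pulsatility_term` naming the metric
#'   column, and `shape` for the gamma model or `sd` for Gaussian models).
#' @param metric_distributions Per-segment list with `pi = c(mean, sd)` and
#'   `fvp = c(mean, sd)` (R-R-standardized scale).
#' @param covariates Named list of covariate distribution settings; see the
#'   defaults in the function body.
#' @param svd_features Named list controlling Fazekas cutpoints, lacune /
#'   recent-infarct prevalences, microbleed rate and the loading of the
#'   shared WMH-severity latent on each feature.
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(n_subjects = 89, seed = 1L,
                          missing_rate = 0.05, followup_rate = 0.539,
                          wmh_model = list(intercept = -3.0, age = 0.06,
                                           sex = 0, map = 0,
                                           hypertension = 0.83,
                                           tcbf = -0.006, pulsatility = 1.67,
                                           pulsatility_term = "ica_fvp",
                                           shape = 1.2),
                          tbv_model = list(intercept = 68, age = -0.34,
                                           sex = 4.17, map = 0.09,
                                           hypertension = 0, tcbf = 0.02,
                                           pulsatility = 0,
                                           pulsatility_term = "ica_fvp",
                                           sd = 5),
                          cognition_model = list(intercept = 40.8,
                                                 age = -0.33, sex = 3.84,
                                                 map = -0.13,
                                                 hypertension = 0, tcbf = 0,
                                                 pulsatility = -4.4,
                                                 pulsatility_term = "m1_pi",
                                                 sd = 3),
                          metric_distributions = list(
                            ica = list(pi = c(1.26, 0.37), fvp = c(0.47, 0.15)),
                            m1 = list(pi = c(1.28, 0.37), fvp = c(0.28, 0.11)),
                            m3 = list(pi = c(1.40, 0.51), fvp = c(0.06, 0.02))),
                          covariates = list(
                            age_mean = 70.2, age_sd = 8.9,
                            female_prob = 0.303,
                            dbp_mean = 78.4, dbp_sd = 10.2,
                            pulse_pressure_mean = 69, pulse_pressure_sd = 18,
                            hypertension_prob = 0.865,
                            antihypertensive_probs = c(beta_blocker = 0.39,
                                                       raas = 0.64,
                                                       ccb = 0.36,
                                                       diuretic = 0.33),
                            stroke_prob = 0.719, nihss_lambda = 1,
                            tcbf_mean = 600, tcbf_sd = 110,
                            icv_mean = 1450, icv_sd = 120,
                            age_metric_cor = 0.4, subject_metric_cor = 0.6),
                          svd_features = list(
                            wmh_latent_loading = 0.87,
                            fazekas_pv_cut = c(0.25, 0.60, 0.86),
                            fazekas_dwm_cut = c(0.30, 0.67, 0.90),
                            lacune_prob = 0.135, infarct_prob = 0.17,
                            feature_latent_loading = 1.0,
                            microbleed_log_mean = log(0.6),
                            microbleed_latent_loading = 0.9)) {
  if (!is_scalar_num(n_subjects) || n_subjects < 1) {
    stopf("n_subjects must be >= 1")
  }
  for (r in c(missing_rate, followup_rate)) {
    if (!is_scalar_num(r) || r < 0 || r > 1) stopf("rates must be in [0, 1]")
  }
  if (wmh_model$shape <= 0) stopf("gamma shape must be positive")
  if (tbv_model$sd <= 0 || cognition_model$sd <= 0) {
    stopf("residual SDs must be positive")
  }
  for (m in list(wmh_model, tbv_model, cognition_model)) {
    need <- c("intercept", "age", "sex", "map", "hypertension", "tcbf",
              "pulsatility", "pulsatility_term")
    miss <- setdiff(need, names(m))
    if (length(miss)) stopf("outcome model missing coefficients: %s",
                            paste(miss, collapse = ", "))
    if (!all(vapply(m[setdiff(need, "pulsatility_term")], is_scalar_num,
                    logical(1)))) {
      stopf("outcome model coefficients must be finite scalars")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 missing_rate = missing_rate, followup_rate = followup_rate,
                 wmh_model = wmh_model, tbv_model = tbv_model,
                 cognition_model = cognition_model,
                 metric_distributions = metric_distributions,
                 covariates = covariates, svd_features = svd_features),
            class = "cohort_params")
}

## Linear predictor of one outcome model on the generated covariates.
linpred <- function(m, d, puls) {
  m$intercept + m$age * d$age + m$sex * d$sex_female + m$map * d$map +
    m$hypertension * d$hypertension + m$tcbf * d$tcbf + m$pulsatility * puls
}

#' Generate a synthetic cohort with known generative truth
#'
#' Draws covariates, per-side segment pulsatility metrics (correlated with
#' age and a shared subject-level pulsatility latent), bilateral-averaged
#' metrics with contralateral fallback under the configured missingness,
#' outcomes from the generative GLMs (gamma/log for WMH %ICV,
#' Gaussian/identity for TBV %ICV and the cognitive aggregate), tissue
#' volumes consistent with the outcome percentages, small-vessel-disease
#' features tied to a latent WMH-severity score, and the eight cognitive
#' subtest scores consistent with the aggregate.
#'
#' @param params A [cohort_params] object.
#' @return A `data.frame` with one row per subject and attribute `"truth"`
#'   holding the generative coefficient lists (also written as the
#'   `--truth` sidecar by the pipeline).
#' @examples
#' co <- generate_cohort(cohort_params(n_subjects = 50, seed = 7))
#' mean(co$svd)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  cv <- p$covariates
  n <- p$n_subjects
  with_seed(p$seed, {
    d <- data.frame(subject_id = sprintf("S%04d", seq_len(n)))
    d$age <- rnorm(n, cv$age_mean, cv$age_sd)
    d$sex <- ifelse(runif(n) < cv$female_prob, "F", "M")
    d$sex_female <- as.integer(d$sex == "F")
    d$dbp <- rnorm(n, cv$dbp_mean, cv$dbp_sd)
    pp <- pmax(10, rnorm(n, cv$pulse_pressure_mean, cv$pulse_pressure_sd))
    d$sbp <- d$dbp + pp
    d$map <- d$dbp + (d$sbp - d$dbp) / 3
    d$hypertension <- as.integer(runif(n) < cv$hypertension_prob)
    for (cl in names(cv$antihypertensive_probs)) {
      d[[cl]] <- as.integer(runif(n) < cv$antihypertensive_probs[[cl]])
    }
    d$diagnosis <- ifelse(runif(n) < cv$stroke_prob, "stroke", "TIA")
    d$nihss <- rpois(n, cv$nihss_lambda)
    d$tcbf <- rnorm(n, cv$tcbf_mean, cv$tcbf_sd)

    ## Segment metrics: shared age link + subject pulsatility latent + side noise
    z_age <- (d$age - cv$age_mean) / cv$age_sd
    u <- rnorm(n)
    w_a <- cv$age_metric_cor
    w_u <- cv$subject_metric_cor
    w_e <- sqrt(max(1 - w_a^2 - w_u^2, 0.05))
    for (seg in names(p$metric_distributions)) {
      for (met in c("pi", "fvp")) {
        ms <- p$metric_distributions[[seg]][[met]]
        base <- paste(seg, met, sep = "_")
        for (side in c("left", "right")) {
          val <- ms[1] + ms[2] * (w_a * z_age + w_u * u + w_e * rnorm(n))
          val <- pmax(val, 0.01)
          val[runif(n) < p$missing_rate] <- NA_real_
          d[[paste(base, side, sep = "_")]] <- val
        }
        l <- d[[paste(base, "left", sep = "_")]]
        r <- d[[paste(base, "right", sep = "_")]]
        d[[base]] <- rowMeans(cbind(l, r), na.rm = TRUE)
        d[[base]][is.na(l) & is.na(r)] <- NA_real_
      }
    }

    ## Outcomes from the generative GLMs
    eta_wmh <- linpred(p$wmh_model, d, d[[p$wmh_model$pulsatility_term]])
    shape <- p$wmh_model$shape
    d$wmh_pct_icv <- NA_real_
    ok <- is.finite(eta_wmh)  # missing pulsatility propagates as missing WMH
    d$wmh_pct_icv[ok] <- pmax(rgamma(sum(ok), shape = shape,
                                     rate = shape / exp(eta_wmh[ok])), 1e-4)
    eta_tbv <- linpred(p$tbv_model, d, d[[p$tbv_model$pulsatility_term]])
    d$tbv_pct_icv <- eta_tbv + rnorm(n, 0, p$tbv_model$sd)
    eta_cog <- linpred(p$cognition_model, d,
                       d[[p$cognition_model$pulsatility_term]])
    cog <- eta_cog + rnorm(n, 0, p$cognition_model$sd)

    ## Tissue volumes consistent with the percentage outcomes
    d$icv <- pmax(rnorm(n, cv$icv_mean, cv$icv_sd), 800)
    tbv_ml <- d$tbv_pct_icv / 100 * d$icv
    d$gm <- 0.55 * tbv_ml
    d$wm <- 0.45 * tbv_ml
    d$csf <- d$icv - tbv_ml
    d$wmh_ml <- d$wmh_pct_icv / 100 * d$icv

    ## SVD features from a latent severity tied to log WMH burden
    sf <- p$svd_features
    lw <- log(d$wmh_pct_icv)
    s <- sf$wmh_latent_loading * (lw - mean(lw, na.rm = TRUE)) /
      sd(lw, na.rm = TRUE) +
      sqrt(1 - sf$wmh_latent_loading^2) * rnorm(n)
    s[is.na(s)] <- 0
    d$fazekas_pv <- findInterval(s, qnorm(sf$fazekas_pv_cut))
    s2 <- 0.9 * s + sqrt(1 - 0.81) * rnorm(n)
    d$fazekas_dwm <- findInterval(s2, qnorm(sf$fazekas_dwm_cut))
    d$fazekas_total <- d$fazekas_pv + d$fazekas_dwm
    b <- sf$feature_latent_loading
    d$lacune <- runif(n) < plogis(qlogis(sf$lacune_prob) + b * s)
    d$recent_subcortical_infarct <-
      runif(n) < plogis(qlogis(sf$infarct_prob) + b * s)
    d$microbleed_count <- rpois(n, exp(sf$microbleed_log_mean +
                                         sf$microbleed_latent_loading * s))
    d$svd <- classify_svd(d$fazekas_total, d$recent_subcortical_infarct,
                          d$lacune, d$microbleed_count)

    ## Cognitive subtests consistent with the aggregate; follow-up subset
    followup <- runif(n) < p$followup_rate
    norms <- cognitive_norms()
    k <- nrow(norms)
    e <- matrix(rnorm(n * k, 0, 0.8), n, k)
    e <- e - rowMeans(e)
    zmat <- cog / k + e
    for (j in seq_len(k)) {
      sc <- norms$mean[j] + norms$orientation[j] * zmat[, j] * norms$sd[j]
      sc[!followup] <- NA_real_
      d[[norms$test[j]]] <- sc
    }
    d$aggregate_z <- ifelse(followup, cog, NA_real_)

    truth <- list(seed = p$seed, n_subjects = n,
                  wmh_model = p$wmh_model, tbv_model = p$tbv_model,
                  cognition_model = p$cognition_model,
                  missing_rate = p$missing_rate,
                  followup_rate = p$followup_rate)
    attr(d, "truth") <- truth
    d
  })
}

#' Intracranial volume arithmetic
#'
#' ICV is the sum of grey matter, white matter and CSF volumes; total brain
#' volume is grey plus white matter. TBV and WMH volume are expressed as a
#' percentage of ICV.
#'
#' @param gm,wm,csf,wmh Tissue and lesion volumes, ml (vectorized,
#'   non-negative; `gm + wm + csf` must be positive).
#' @return A `data.frame` with `icv` (ml), `tbv_pct_icv` and `wmh_pct_icv`.
#' @examples
#' compute_volume_fractions(600, 500, 400, 15)
#' @export
compute_volume_fractions <- function(gm, wm, csf, wmh) {
  vols <- cbind(gm, wm, csf, wmh)
  if (any(!is.finite(vols)) || any(vols < 0)) {
    stopf("volumes must be finite and non-negative")
  }
  icv <- gm + wm + csf
  if (any(icv <= 0)) stopf("intracranial volume must be positive")
  data.frame(icv = icv, tbv_pct_icv = 100 * (gm + wm) / icv,
             wmh_pct_icv = 100 * wmh / icv)
}

#' Small vessel disease composite classification
#'
#' SVD is present if any of: total Fazekas score >= 4, a small recent
#' subcortical infarct, a lacune, or more than 2 cerebral microbleeds
#' (strict inequality).
#'
#' @param fazekas_total Total Fazekas score, 0-6 (periventricular + deep).
#' @param recent_subcortical_infarct,lacune Logical (or 0/1).
#' @param microbleed_count Non-negative integer count.
#' @return Logical vector. All four features are required; a missing value
#'   in any of them is an error.
#' @examples
#' classify_svd(4, FALSE, FALSE, 0)   # TRUE (Fazekas threshold)
#' classify_svd(3, FALSE, FALSE, 2)   # FALSE (strict > 2 microbleeds)
#' @export
classify_svd <- function(fazekas_total, recent_subcortical_infarct, lacune,
                         microbleed_count) {
  args <- list(fazekas_total, recent_subcortical_infarct, lacune,
               microbleed_count)
  if (any(vapply(args, function(x) any(is.na(x)), logical(1)))) {
    stopf("classify_svd requires all four features; missing values present")
  }
  if (any(fazekas_total < 0 | fazekas_total > 6)) {
    stopf("fazekas_total must be in 0..6")
  }
  if (any(microbleed_count < 0)) stopf("microbleed_count must be >= 0")
  fazekas_total >= 4 | as.logical(recent_subcortical_infarct) |
    as.logical(lacune) | microbleed_count > 2
}

#' Normative table for the cognitive test battery
#'
#' Means, SDs and scoring orientation for the eight subtests (two-choice
#' reaction, Stroop congruent/incongruent, ten-word list, delayed recall,
#' delayed recognition, trail making A and B). Orientation is -1 for timed
#' tests (lower is better) and +1 otherwise. The default values are
#' synthetic norms on plausible clinical scales; within-cohort
#' standardization can be used instead by passing norms computed from the
#' sample.
#'
#' @return A `data.frame` with columns `test`, `mean`, `sd`, `orientation`.
#' @export
cognitive_norms <- function() {
  data.frame(
    test = c("two_choice_reaction", "stroop_congruent", "stroop_incongruent",
             "ten_word_list", "delayed_recall", "delayed_recognition",
             "trail_making_a", "trail_making_b"),
    mean = c(520, 700, 1000, 7.5, 6.5, 9.0, 40, 90),
    sd = c(90, 120, 180, 1.5, 1.8, 1.2, 12, 35),
    orientation = c(-1, -1, -1, 1, 1, 1, -1, -1)
  )
}

#' Cognitive Z-score aggregate
#'
#' Each subtest result is converted to a Z-score against its norm,
#' `z = orientation * (score - mean) / sd`, with orientation -1 for timed
#' tests so that higher always means better; the aggregate is the sum of
#' the eight Z-scores.
#'
#' @param scores Named numeric vector of subtest scores (names matching
#'   `norms$test`).
#' @param norms Normative table as from [cognitive_norms()]; SDs must be
#'   positive.
#' @param missing_policy `"missing"` (default: any absent subtest makes the
#'   aggregate `NA`) or `"available"` (sum over the subtests present).
#' @return The aggregate Z-score (dimensionless).
#' @examples
#' nm <- cognitive_norms()
#' sc <- setNames(nm$mean, nm$test)
#' aggregate_cognition(sc)  # 0: all at norm
#' @export
aggregate_cognition <- function(scores, norms = cognitive_norms(),
                                missing_policy = c("missing", "available")) {
  missing_policy <- match.arg(missing_policy)
  if (any(norms$sd <= 0)) stopf("norm SDs must be positive")
  if (is.null(names(scores))) stopf("scores must be a named vector")
  z <- numeric(nrow(norms))
  present <- logical(nrow(norms))
  for (j in seq_len(nrow(norms))) {
    s <- if (norms$test[j] %in% names(scores)) scores[[norms$test[j]]] else NA_real_
    present[j] <- !is.na(s)
    z[j] <- if (present[j]) {
      norms$orientation[j] * (s - norms$mean[j]) / norms$sd[j]
    } else NA_real_
  }
  if (!all(present)) {
    if (missing_policy == "missing") return(NA_real_)
    return(sum(z[present]))
  }
  sum(z)
}

#' Simulate a pair of ordinal raters
#'
#' Each rater observes the latent severity plus a rater-specific bias and
#' independent Gaussian noise; ratings are rounded and clamped to the 0-6
#' scale (total Fazekas range). Fixture generator for interrater-agreement
#' (ICC) testing.
#'
#' @param true_scores Per-subject latent severities.
#' @param rater_sd SD of rater noise (>= 0).
#' @param rater_bias Systematic bias of rater B relative to rater A.
#' @param seed Integer seed.
#' @return A list with integer vectors `rater_a` and `rater_b`.
#' @export
simulate_rater_pair <- function(true_scores, rater_sd, rater_bias = 0,
                                seed = 1L) {
  if (!is.numeric(rater_sd) || rater_sd < 0) stopf("rater_sd must be >= 0")
  n <- length(true_scores)
  with_seed(seed, {
    rate <- function(bias) {
      as.integer(pmin(6, pmax(0, round(true_scores + bias +
                                         rnorm(n, 0, rater_sd)))))
    }
    list(rater_a = rate(0), rater_b = rate(rater_bias))
  })
}
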