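#' Parameters of the synthetic cardiac flow waveform
#'
#' Parametric model of an intracranial arterial flow waveform over one
#' cardiac cycle: a baseline mean flow, a unimodal systolic pulse (periodized
#' Gaussian bump, zero cycle mean, unit peak), an optional dicrotic bump,
#' and optional additive Gaussian noise. Defaults emulate a cavernous-ICA
#' waveform with R-R-standardized PI near 1.26 and FVP near 0.47 ml, the
#' cohort-scale magnitudes reported for that segment.
#'
#' @param mean_flow Cycle mean flow, ml/s (> 0).
#' @param pulse_amplitude Peak systolic excess over the mean, ml/s.
#' @param systolic_peak_time Peak location as a fraction of the cycle (0-1).
#' @param peak_width Full width at half maximum of the systolic bump,
#'   fraction of the cycle (0-1).
#' @param dicrotic_amplitude Amplitude of the secondary (dicrotic) bump,
#'   ml/s; 0 disables it.
#' @param dicrotic_time Dicrotic bump location, fraction of the cycle.
#' @param rr_interval R-R interval, seconds.
#' @param rr_jitter_sd SD of beat-to-beat R-R variation, seconds (used by
#'   [rr_sequence()]).
#' @param noise_sd SD of additive sampling noise, ml/s.
#' @param seed Integer seed for the noise / jitter streams.
#' @return A `waveform_params` object (validated list).
#' @export
waveform_params <- function(mean_flow = 4.5, pulse_amplitude = 5.0,
                            systolic_peak_time = 0.16, peak_width = 0.12,
                            dicrotic_amplitude = 0.8, dicrotic_time = 0.45,
                            rr_interval = 0.9, rr_jitter_sd = 0.0,
                            noise_sd = 0.0, seed = 1L) {
  p <- list(mean_flow = mean_flow, pulse_amplitude = pulse_amplitude,
            systolic_peak_time = systolic_peak_time, peak_width = peak_width,
            dicrotic_amplitude = dicrotic_amplitude,
            dicrotic_time = dicrotic_time, rr_interval = rr_interval,
            rr_jitter_sd = rr_jitter_sd, noise_sd = noise_sd,
            seed = as.integer(seed))
  for (f in setdiff(names(p), "seed")) {
    if (!is_scalar_num(p[[f]])) stopf("waveform_params$%s must be a finite scalar", f)
  }
  if (p$mean_flow <= 0) stopf("mean_flow must be positive")
  if (p$systolic_peak_time <= 0 || p$systolic_peak_time >= 1) {
    stopf("systolic_peak_time must be in (0, 1)")
  }
  if (p$peak_width <= 0 || p$peak_width >= 1) stopf("peak_width must be in (0, 1)")
  if (p$rr_interval <= 0) stopf("rr_interval must be positive")
  if (p$rr_jitter_sd < 0 || p$noise_sd < 0) stopf("SD parameters must be >= 0")
  structure(p, class = "waveform_params")
}

## Zero-cycle-mean, unit-peak periodized Gaussian bump at phase centre/width
## (both as cycle fractions; width = FWHM). Vectorized over phase.
pulse_bump <- function(phase, centre, width) {
  sigma <- width / (2 * sqrt(2 * log(2)))
  ## wrap to nearest periodic image
  d <- (phase - centre) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  b <- exp(-0.5 * (d / sigma)^2)
  ## cycle mean of the fully periodized bump is the Gaussian's total mass
  mb <- min(sigma * sqrt(2 * pi), 1)
  (b - mb) / (1 - mb)
}

#' Continuous synthetic waveform as a function of time
#'
#' Returns the noise-free periodic flow waveform `Q(t)` (ml/s) implied by a
#' [waveform_params] object, as a vectorized function of time in seconds
#' (period `rr_interval`). Used as ground truth for gated-reconstruction
#' experiments.
#'
#' @param params A [waveform_params] object.
#' @return `function(t)` returning flow in ml/s.
#' @export
waveform_function <- function(params) {
  stopifnot(inherits(params, "waveform_params"))
  p <- params
  force(p)
  function(t) {
    phase <- (t / p$rr_interval) %% 1
    p$mean_flow +
      p$pulse_amplitude * pulse_bump(phase, p$systolic_peak_time, p$peak_width) +
      p$dicrotic_amplitude * pulse_bump(phase, p$dicrotic_time,
                                        p$peak_width * 1.6)
  }
}

#' Generate a sampled synthetic flow waveform
#'
#' Samples the parametric waveform model at `n_samples` uniform time points
#' over one cycle, adding Gaussian noise if `noise_sd > 0`. Deterministic
#' given `params$seed`.
#'
#' @param params A [waveform_params] object.
#' @param n_samples Number of samples per cycle (>= 3); 20 matches the
#'   gated-reconstruction phase count.
#' @param artery,side Labels passed to [flow_waveform()].
#' @return A [flow_waveform].
#' @examples
#' wf <- generate_waveform(waveform_params(noise_sd = 0), n_samples = 20)
#' compute_pi(wf)
#' @export
generate_waveform <- function(params, n_samples = 20, artery = "ICA",
                              side = "unknown") {
  stopifnot(inherits(params, "waveform_params"))
  if (!is_scalar_num(n_samples) || n_samples < 3) {
    stopf("n_samples must be >= 3")
  }
  n_samples <- as.integer(n_samples)
  times <- seq(0, params$rr_interval, length.out = n_samples + 1)[seq_len(n_samples)]
  q <- waveform_function(params)(times)
  if (params$noise_sd > 0) {
    q <- q + with_seed(params$seed, rnorm(n_samples, 0, params$noise_sd))
  }
  flow_waveform(times, q, params$rr_interval, artery = artery, side = side)
}

#' Beat-to-beat R-R interval sequence
#'
#' Draws `n_beats` R-R intervals around `params$rr_interval` with Gaussian
#' jitter `rr_jitter_sd`, floored at 0.3 s. Deterministic given the seed.
#'
#' @param params A [waveform_params] object.
#' @param n_beats Number of cardiac cycles.
#' @param seed Optional override of `params$seed`.
#' @return Numeric vector of R-R intervals, seconds.
#' @export
rr_sequence <- function(params, n_beats, seed = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  seed <- if (is.null(seed)) params$seed else seed
  with_seed(seed, pmax(0.3, rnorm(n_beats, params$rr_interval,
                                  params$rr_jitter_sd)))
}

#' Retrospectively gated waveform reconstruction
#'
#' Emulates retrospective cardiac gating with temporal interpolation:
#' acquisition samples are drawn at random times across a run of cardiac
#' cycles, each sample is assigned a cardiac phase via its own cycle's R-R
#' interval, and samples are combined into `n_phases` uniform phase bins
#' with triangular (linear-interpolation) weighting between adjacent bin
#' centres. The output cycle uses the mean R-R interval.
#'
#' Averaging within phase bins cannot exceed the true systolic maximum, so
#' narrow systolic peaks are blunted and PI is underestimated relative to
#' dense sampling; the cumulative-integral FVP is much less sensitive to
#' this temporal blurring.
#'
#' @param continuous_waveform Vectorized `function(t)` giving flow (ml/s)
#'   over one cycle of length the reference R-R interval.
#' @param rr_sequence Positive R-R intervals of the acquired cycles, s.
#' @param n_phases Number of reconstructed cardiac phases (default 20).
#' @param n_acq Total number of acquisition samples across the run.
#' @param seed Integer seed for the random acquisition times.
#' @param artery,side Labels for the output waveform.
#' @return A [flow_waveform] with `n_phases` samples at phase-bin centres
#'   and `rr_interval = mean(rr_sequence)`.
#' @export
gated_reconstruction <- function(continuous_waveform, rr_sequence,
                                 n_phases = 20, n_acq = 4000, seed = 1L,
                                 artery = "ICA", side = "unknown") {
  if (!is.function(continuous_waveform)) {
    stopf("continuous_waveform must be a function of time")
  }
  if (length(rr_sequence) < 1 || any(!is.finite(rr_sequence)) ||
      any(rr_sequence <= 0)) {
    stopf("rr_sequence must be non-empty and positive")
  }
  n_phases <- as.integer(n_phases)
  rr_ref <- mean(rr_sequence)
  total <- sum(rr_sequence)
  starts <- cumsum(c(0, rr_sequence[-length(rr_sequence)]))
  t_acq <- with_seed(seed, sort(runif(n_acq, 0, total)))
  cyc <- findInterval(t_acq, starts)
  phase <- (t_acq - starts[cyc]) / rr_sequence[cyc]  # in [0, 1)
  vals <- continuous_waveform(phase * rr_ref)
  ## triangular weights to the two adjacent phase-bin centres (periodic)
  centres <- (seq_len(n_phases) - 0.5) / n_phases
  dphi <- 1 / n_phases
  lower <- floor(phase / dphi - 0.5)          # index offset of bin below
  frac <- phase / dphi - 0.5 - lower          # in [0, 1)
  b0 <- (lower %% n_phases) + 1
  b1 <- ((lower + 1) %% n_phases) + 1
  wsum <- numeric(n_phases)
  vsum <- numeric(n_phases)
  add <- function(b, w) {
    s <- tapply(w, b, sum)
    i <- as.integer(names(s))
    wsum[i] <<- wsum[i] + as.numeric(s)
    sv <- tapply(w * vals, b, sum)
    vsum[i] <<- vsum[i] + as.numeric(sv)
  }
  add(b0, 1 - frac)
  add(b1, frac)
  if (any(wsum <= 0)) {
    stopf("gated reconstruction failed: %d of %d phase bins received no samples",
          sum(wsum <= 0), n_phases)
  }
  flow_waveform(centres * rr_ref, vsum / wsum, rr_ref,
                artery = artery, side = side)
}
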