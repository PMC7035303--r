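## Shared fixtures and independent oracles for the test suite.

## Sine waveform: Q(t) = q0 + a sin(2*pi*t/rr), n samples over one cycle.
## Closed forms: mean = q0, PI = 2a/q0, FVP = a*rr/pi.
sine_waveform <- function(n, q0 = 5, a = 2, rr = 1, ...) {
  t <- seq(0, rr, length.out = n + 1)[seq_len(n)]
  flow_waveform(t, q0 + a * sin(2 * pi * t / rr), rr, ...)
}

## Randomized smooth-ish waveform on a jittered uniform grid (the sampling
## regime of gated reconstructions; coincident samples excluded).
random_waveform <- function(n = NULL, rr = 1) {
  if (is.null(n)) n <- sample(12:40, 1)
  base <- seq(0, 0.95 * rr, length.out = n + 1)[seq_len(n)]
  t <- base + runif(n, 0, 0.4) * (base[2] - base[1])
  q <- 5 + 2 * rnorm(n)
  flow_waveform(t, q, rr)
}

## Dense-quadrature oracle for cycle mean and FVP on the same periodic
## cubic-spline interpolant the implementation uses: trapezoidal
## integration at n_dense points (independent of the closed-form segment
## integration path under test).
dense_oracle <- function(wf, n_dense = 1e6) {
  x <- c(wf$times, wf$times[1] + wf$rr_interval)
  f <- stats::splinefun(x, c(wf$flow_rates, wf$flow_rates[1]),
                        method = "periodic")
  tt <- seq(x[1], x[length(x)], length.out = n_dense)
  q <- f(tt)
  dt <- diff(tt)
  seg <- (q[-n_dense] + q[-1]) / 2 * dt
  m <- sum(seg) / wf$rr_interval
  v <- c(0, cumsum(seg - m * dt))
  list(mean = m, fvp = max(v) - min(v))
}

## Brute-force ICC(2,1) via two-way ANOVA mean squares from aov().
icc_oracle <- function(a, b) {
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(seq_along(a), 2)),
                  rater = factor(rep(1:2, each = length(a))))
  ms <- anova(aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  n <- length(a)
  k <- 2
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

## Small cohort shared across association tests (generated once per run).
test_cohort <- local({
  co <- NULL
  function(n = 2000, seed = 424242) {
    if (is.null(co)) co <<- generate_cohort(cohort_params(n_subjects = n,
                                                          seed = seed))
    co
  }
})
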