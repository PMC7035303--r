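---
title: "Quantifying cerebral arterial pulsatility: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral arterial pulsatility: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowpulse)
```

## The problem

Large cerebral arteries normally damp the cardiac pressure pulse before it
reaches the microcirculation (the Windkessel effect). With arterial
stiffening, more pulsatile energy is transmitted distally, and excessive
pulsatile stress on small vessels is a candidate mechanism for cerebral
small vessel disease (SVD): white matter hyperintensities (WMH), lacunes,
microbleeds, atrophy and vascular cognitive impairment. 4D flow MRI
measures time-resolved velocity fields across the whole intracranial
vasculature in one acquisition, from which per-artery flow-rate waveforms
Q(t) are extracted along vessel centerlines.

`flowpulse` implements the waveform-level pulsatility measures, a
synthetic data layer that emulates how the acquisition shapes them, and
the multivariable association analysis connecting them to imaging and
cognitive outcomes.

## Waveform metrics

A `flow_waveform` holds one cardiac cycle: sample times (s), flow rates
(ml/s), and the R-R interval; the cycle is treated as periodic (the last
sample connects back to the first).

**Pulsatility index (Gosling).** `PI = (max Q - min Q) / mean(Q)`.
Extremes are taken over the raw sampled points with no additional
smoothing: 20-phase gated reconstructions are already temporally smoothed
by the reconstruction itself, and further smoothing would double-count
that blunting. PI is undefined (an error) when the cycle mean flow is not
positive, since net-retrograde flow is not physiological in the arteries
considered here.

**Flow volume pulsatility.** `V(t)` is the running integral of the
mean-subtracted waveform; `FVP = max V - min V` (ml). V is, up to the
compliance of the intervening tree, the cyclic storage volume of the
downstream vasculature, so FVP estimates the per-cycle volume expansion
distal to the measurement plane.

**R-R standardization.** Both measures are divided by the R-R interval in
seconds, i.e. normalized to a 1-s reference cycle. The motivation is
exposure per unit time: at equal per-cycle expansion, a faster heart
subjects the distal bed to more pulsatile stress, and division by the
cycle length makes the standardized measure increase as the cycle
shortens. The alternative convention (multiplication) moves the measure
the wrong way under this rationale, so division is used; at cycle lengths
near 0.9-1 s the two differ by little in practice.

**Bilateral handling.** Paired segments (ICA, M1, M3) are summarized as
the left/right mean; a missing side falls back to the contralateral
value; both sides missing propagates as a missing metric. tCBF is the sum
of mean flows of both ICAs and the basilar artery, with no fallback (all
three vessels are required).

### Numerical integration

Cycle means and cumulative volumes are integrals of a waveform known only
at 20 phases. The package interpolates the samples with a *periodic cubic
spline* and integrates it in closed form: each segment's cubic (Hermite
form from the spline's values and derivatives) has an exact polynomial
antiderivative, giving V at the sample knots, and interior extrema of V -
where the mean-subtracted flow crosses zero inside a segment - are
located as real roots of the segment cubic and evaluated exactly. Node
extremes, the periodic closing segment, and interior extrema are all
considered.

The reason for spline rather than piecewise-linear (trapezoidal)
integration is accuracy at 20 phases: the trapezoid rule's O(h^2) bias on
partial-cycle integrals is material at h = 1/20 of a cycle (for a pure
sine it biases FVP by about 0.8%), while the spline integral is O(h^4)
(about 0.001% for the same sine; the package's acceptance checks bound
both metrics at 0.5% at 20 samples and 1e-4 at 1000). Metrics computed on
degenerate inputs behave predictably: a constant waveform has FVP exactly
0, and FVP is invariant to adding any constant to Q and scales linearly
with Q's amplitude.

Metrics are computed on the six-voxel-averaged segment waveform, not
per-voxel and then averaged: the averaged waveform is the quantity the
centerline measurement convention defines, and averaging before the
nonlinear max/min operations avoids mixing voxel-level discretization
noise into the extremes.

## Synthetic flow layer

**Waveform model.** `Q(t) = Q0 + A g(t) + dicrotic + noise`, where g is a
periodized Gaussian bump (FWHM expressed as a fraction of the cycle)
minus its cycle mean, normalized to unit peak, so the cycle mean is Q0
regardless of the pulse shape. Defaults (`mean_flow` 4.5 ml/s,
`pulse_amplitude` 5.0 ml/s, peak at 16% of the cycle, FWHM 12%, dicrotic
bump 0.8 ml/s at 45%, RR 0.9 s) were set so that the *gated 20-phase*
measurement of the default waveform lands at the cavernous-ICA-typical
standardized PI of about 1.26 1/s and FVP of about 0.47-0.49 ml/s - the
gated values, because cohort-reported metrics are themselves measurements
on 20-phase reconstructions. Jointly matching PI about 1.26, FVP about
0.47 ml, mean flow about 4.5 ml/s and RR 0.9 s forces an effective
positive-lobe width near 10-12% of the cycle, so the narrow default peak
is a property of the magnitudes being emulated, not a free choice.

**Gated reconstruction.** Retrospective gating is emulated directly in
phase space: acquisition samples are drawn at seeded-random times across
a run of cardiac cycles (default 40 beats, 4000 samples), each sample is
assigned a cardiac phase through its own cycle's R-R interval, and
samples are combined into 20 uniform phase bins with triangular
(linear-interpolation) weights between adjacent bin centres. Empty bins
are an error. Because bin averages cannot exceed the true systolic
maximum, narrow peaks are blunted: at a peak FWHM of 5% of the cycle the
reconstructed PI is about 35% below the dense-sampling PI while FVP is
within a few tenths of a percent - the mechanism by which 20-phase
acquisitions underestimate PI, and the core argument for FVP as the more
acquisition-robust measure. No k-space simulation, eddy currents or
background phase errors are modelled.

**Vessel phantom.** A tube of constant radius around an ordered
centerline on an isotropic grid, with a fully developed (parabolic)
Poiseuille profile at every instant: `v(r, t) = 2 Q(t) / (pi R^2) (1 -
r^2/R^2)` along the local tangent. Instantaneous Poiseuille flow gives
closed-form truth at every voxel; Womersley (pulsatile boundary-layer)
profiles are deliberately out of scope. Velocities above the VENC
(default 110 cm/s) are a configuration error, or wrap into
[-VENC, VENC) when aliasing is enabled. Cross-sectional flow sums
tangent-projected velocities over voxel centres within half a voxel of
the section plane times the voxel area; segment flow averages six
consecutive centerline voxels (the segment-length convention; the window
start is a parameter since the anatomical positioning within a named
segment is a free choice). At 0.5 mm voxels and R = 2.5 mm the
construction truth is recovered within 0.3% across all window voxels and
phases, and the discretization error falls by more than half when the
voxel size is halved.

## Synthetic cohort

The generator produces an acute stroke/TIA cohort (default n = 89) with
covariates at cohort-typical values: age 70.2 (8.9) years, 30% women,
hypertension 86%, antihypertensive classes at their observed prevalences,
MAP computed as `dbp + (sbp - dbp)/3` (the standard clinical formula; no
other definition is implied by the modelled magnitudes), tCBF in ml/min
(mean 600, SD 110 - the scale on which a tCBF coefficient of -0.006 per
unit is plausible). Segment metrics (PI/FVP for ICA, M1, M3) are drawn
around their cohort-typical means with an age loading of 0.4 and a shared
subject-level pulsatility latent, per side, with 5% per-side missingness
and bilateral averaging with fallback applied exactly as in the metrics
module.

Outcomes follow the association models' own structure, with known
generative coefficients recorded in a truth sidecar:

- WMH %ICV ~ Gamma(shape 1.2) with log mean linear in age, sex, MAP,
  hypertension, tCBF and ICA-FVP (default coefficient 1.67); values are
  floored at 1e-4 %ICV so the gamma support holds.
- TBV %ICV and the cognitive aggregate are Gaussian with identity-link
  predictors (default pulsatility effects: 0 on TBV, -4.4 of M1-PI on
  cognition); cognition is observed for ~54% of subjects, emulating
  follow-up participation.
- Tissue volumes are generated consistently (ICV = GM + WM + CSF; TBV% and
  WMH% recompute exactly), Fazekas scores are cut from a latent severity
  correlated 0.87 with log WMH, and lacunes/infarcts/microbleeds load on
  the same latent with marginal rates near their cohort frequencies. The
  latent loadings were calibrated once so that the SVD composite
  (Fazekas total >= 4, or recent subcortical infarct, or lacune, or > 2
  microbleeds) has prevalence in the 46 +/- 5% band at n = 5000.
- Eight cognitive subtest scores are generated consistently with the
  stored aggregate through the normative table (timed tests oriented so
  lower is better), so the Z-aggregation round-trips exactly. The default
  norms are synthetic values on plausible clinical scales; within-sample
  standardization can be substituted by passing sample-derived norms.

What passing tests on this cohort do *not* show: real covariate
correlation structure (covariates are near-independent by design, except
the age links), real WMH zero-inflation, measurement error in pulsatility
shared across segments, or selection effects in follow-up participation
(missingness is completely at random here).

## Association analysis

One GLM per (outcome, pulsatility term): gamma with log link for the
right-skewed WMH burden, Gaussian with identity link for TBV and
cognition; basic covariates age, sex (female = 1), MAP, hypertension
(present = 1), tCBF; pulsatility terms (R-R-standardized, bilateral)
entered one at a time; M3 excluded from multivariable analysis to limit
comparisons. Fitting is iteratively reweighted least squares (relative
deviance tolerance 1e-8, max 100 iterations) with complete-case deletion;
rank-deficient designs are an error naming the collinear columns;
non-convergence is flagged on the result, not an exception. CIs are Wald
on the coefficient scale (estimate +/- 1.96 SE) - consistent with
symmetric reported intervals - with the gamma dispersion estimated by
Pearson chi-square over residual degrees of freedom (the mainstream GLM
convention). No multiple-testing correction is applied (alpha = 0.05).
The battery runs 12 basic models (4 terms x 3 outcomes), the extended
variants (WMH/TBV + four antihypertensive class indicators - four
separate indicators, not a count; cognition + WMH + TBV), and the SVD
subgroup (WMH and TBV only; cognitive follow-ups are too few in a
subgroup). ICC(2,1) - two-way random effects, single rater, absolute
agreement - is computed from the two-way ANOVA mean squares.

Parameter-recovery behaviour is verified by simulation: with the
generative ICA-FVP coefficient at 1.67, the fitted 95% CI covers truth in
about 95% of 200 replicates at n = 2000, and with the coefficient at 0
the rejection rate at alpha = 0.05 is about 5% over 400 replicates.

## Problem sizes and reproducibility

The shipped demo and the recovery simulations use sizes at which every
behaviour of interest is already resolved: phantoms of 16-30 voxels per
axis at 0.5 mm (refinement check at 0.25 mm), 20 cardiac phases, cohorts
of 300 (demo), 1000-5000 (calibration checks) and 2000 x 200/400
replicates (coverage and type-I). Every stochastic operation takes an
explicit seed; the pipeline derives per-stage substreams from one global
seed so that toggling stages does not shift the others, and a run
manifest records seeds and output hashes - identical configurations give
bit-identical outputs.

## Known limitations

- The phantom is a rigid tube with instantaneous Poiseuille flow: no wall
  compliance, no Womersley flattening, no branching, no background-phase
  or eddy-current artifacts, no angiogram segmentation or automatic
  centerline discovery.
- Venous and CSF pulsatility are out of scope, as are wall shear stress
  and pressure estimation.
- The cohort generator draws volumes and ratings directly as numbers; it
  does not simulate images, lesion masks or the neuropsychological tests
  themselves.
- The association layer is cross-sectional regression only: no causal,
  mediation or longitudinal modelling, and the ordinal regressions for
  periventricular/deep WMH grades are documented but not implemented
  (a standard model attached to a negative finding).
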