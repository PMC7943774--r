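---
title: "Methods: parametric VNS dose-response, reversion correction and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric VNS dose-response, reversion correction and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the numerical and design choices behind
`vnspupil`. It is the package's account of *why* each stage looks the way
it does; the README shows what a run prints.

## The measurement model

A session is a set of continuously sampled channels (pupil area, eyelid
area, eye x/y position, treadmill velocity, optionally an axonal GCaMP
fluorescence trace) plus an ordered table of VNS trains, each defined by
pulse amplitude $A$ (mA), width $W$ (ms), rate $R$ (Hz), onset and a 10 s
duration. Charge per pulse is $C = A \cdot W$ (μC). Intertrain intervals
are drawn uniformly from 106–130 s (mean 118 s), jittered so the animal
cannot anticipate train onset.

### Signal conditioning

Each channel kind has a fixed chain (`condition_channel()`), applied in
this order because interpolation must precede filtering (a blink artifact
smeared by the filter could never be recovered):

1. linear resampling to a common 50 Hz grid (native rates are 143 Hz for
   the eye camera in standard sessions, 15 Hz in imaging sessions);
2. blink/dropout detection: samples where the z-scored first difference
   exceeds 3 in magnitude, merged with frames already flagged missing,
   each bad span padded by 150 ms on both sides;
3. linear interpolation across bad spans (nearest-value extension at the
   edges), with a gap mask recording exactly which samples are synthetic;
4. third-order Butterworth low-pass at 3 Hz, applied forward and
   backward. Zero-phase filtering is a deliberate choice: evoked-latency
   measurements must not be displaced, at the cost that the effective
   magnitude response is the squared one-pass response (checked against
   the closed form $|H(f)|^2 = (1+(f/3)^6)^{-1}$ in the tests);
5. normalization: pupil, eyelid and calcium to percent of the session's
   99.9th percentile; eye position to z-scores; velocity kept in cm/s.
   Calcium additionally gets a single least-squares line removed first
   (photobleaching rundown over the session).

The blink z-threshold (3.0) and pad (150 ms) are configurable
(`vns_config()`); the threshold is a judgment call — the detection rule
itself is what matters downstream, because the artifact flagging keys off
the gap mask.

### Evoked scalars and artifact flags

The evoked response of a trial is the mean of the conditioned signal over
a post-onset response window minus the mean over a pre-onset baseline
window, both half-open. Windows differ by luminance class: standard
sessions use response 2.5–7.5 s and baseline −5–0 s; low-luminance imaging
sessions, where dilations last much longer, use 10–30 s against a 20 s
baseline. Walking metrics use the mean velocity over the 10 s train with a
strict `|speed| > 0.05` cm/s criterion (a trial exactly at the threshold
did not walk). A trial is flagged — never deleted — when more than 25% of
the samples in its measurement windows were interpolated, when its epoch
is truncated by the session edge, or (imaging) when image motion exceeded
2 μm in x or y. The 25% fraction is our operationalization of "could not
reliably measure"; only the outcome rates, not the rule, are identifiable
from published artifact percentages.

## Reversion to the mean

Spontaneous pupil size is strongly autocorrelated and mean-reverting: a
dilated pupil tends to constrict over the next seconds regardless of
stimulation, which anticorrelates baseline and evoked scalars. The
correction (`extract_pseudo_trials()`, `reversion_model()`,
`apply_correction()`) measures that tendency on stimulus-free data: for
each train with at least 30 s of clean pre-onset data, a pseudo onset is
placed so the pseudo response window ends exactly at the true onset, and
pseudo baseline/response scalars are computed with the real windows. A
cubic least-squares fit of pseudo response on pseudo baseline is then
subtracted from every observed response given its observed baseline.

Design points decided here:

- the cubic is fitted to **trial-level** pseudo data; the eight
  equal-count baseline bins are reported as diagnostics only (fitting to
  bin means would discard within-bin information);
- one pseudo trial per real trial, placed as late as possible — this uses
  the data closest in time to the trial it corrects;
- the correction is fitted pooled per experiment kind (a per-session
  override exists), and the provenance check refuses a second application
  to an already-corrected column, which would silently bias responses;
- corrected and uncorrected columns coexist so any analysis can be run
  both ways.

On null-effect synthetic sessions the uncorrected baseline-response slope
is significantly negative and the corrected slope is statistically
indistinguishable from zero; that pair of facts is the module's
acceptance test and is also recomputed by `scripts/acceptance.R`.

## The dose-response surface

Trialwise responses are fitted with the separable log-logistic surface

$$P = \frac{s}{1+(A/a_1)^{-b_1}} \cdot \frac{1}{1+(W/a_2)^{-b_2}} \cdot
      \frac{1}{1+(R/a_3)^{-b_3}}$$

or the reduced charge form $P = s\,(1+(C/a_1)^{-b_1})^{-1}
(1+(R/a_2)^{-b_2})^{-1}$. Each $a_i$ is that factor's half-maximal value;
variance explained is $100(1-SS_{res}/SS_{tot})$ over trials.

Numerical choices:

- **Trial-level objective, evaluated on cells.** Predictions depend on
  the factors only through the unique tested combinations, so the
  trialwise sum of squares equals the count-weighted cell-mean sum of
  squares plus a constant; the optimizer therefore works on ≤ 60 cells
  regardless of the number of repetitions, with no change to the
  estimator.
- **Multi-start bounded L-BFGS-B.** Starts: $s$ at the extreme cell mean,
  $a_i$ at the 25/50/75th percentiles of the tested factor values, $b_i
  \in \{1, 2\}$; bounds $a_i \in [\min/10, 10\max]$, $b_i \in [0.1, 20]$,
  $s \ge 0$ for pupil/calcium and free-signed for eyelid/walking. The
  cross-validated engagement fits use a lighter start grid (midpoints at
  the median only) because they repeat the fit once per fold; bootstrap
  refits warm-start at the full-sample optimum.
- Degenerate inputs: all-zero responses return an $s=0$ fit with a
  warning; constant responses produce variance explained ≈ 0.
- A caveat the tests document: the separable $A \times W$ surface cannot
  represent a function of the product $A\cdot W$ exactly, so on perfectly
  charge-equivalent data the full model retains a small systematic
  deficit (under 1% of variance at realistic noise). "Comparable variance
  explained" is therefore the correct reading of a full-vs-reduced
  comparison, not exact equality.

Charge bins are five equal log10-width intervals spanning the tested
charge range (0.01–0.72 μC for the full grid), labelled no-effect /
optimal / off-target from lowest to highest. Binwise significance uses
two-sided one-sample t tests against zero — except calcium, which is
tested paired against the lowest charge bin, because the calcium region
of interest was itself selected for responsiveness and a test against
zero would be circular. All p-values in a family are Benjamini–Hochberg
adjusted (`bh_fdr()` wraps `stats::p.adjust`; the test suite checks the
rejection set against a brute-force step-up oracle).

The half-maximal charge is the fitted `a1` of the reduced model, with a
trial-resampling bootstrap SD (default 5000 replicates). Two conditions
are compared by pairing their draw vectors by index:
$p = 2\min(\Pr(d\le 0), \Pr(d\ge 0))$, floored at $2/n_{boot}$.

## Engagement and mediation

To relate pupil, calcium and stimulation on a common axis, the engagement
vector $N$ is built by 20-fold cross-validation: each fold's surface is
fitted on the other folds' pupil responses and evaluated at the held-out
trials' parameters, so no trial's $N$ saw that trial's response. Folds
are stratified by charge bin so every training set spans the dose range;
the partition is balanced (fold sizes differ by at most one), which makes
`folds = n` exact leave-one-out.

The mediation analysis then fits three OLS models on non-walking trials:
$P = i_0 + cN$ (total), $Ca = i_1 + aN$, and $P = i_2 + c'N + b\,Ca$.
(The mediator model is the standard form of path analysis; a variant with
the outcome on both sides is not estimable.) The indirect effect is
$a\cdot b$, and $c = c' + ab$ holds exactly for OLS with these regressor
sets — asserted to $10^{-8}$ on every fit. The proportion mediated
$ab/c$ is reported only when $|c| \ge 2\,SE(c)$; near-zero total effects
make the ratio meaningless. Bootstrap inference resamples trials with
replacement (sessions are not resampled: the imaging dataset has too few
sessions for a session bootstrap to be stable) and reports the fraction
of draws below zero per effect.

## The synthetic-session generator

`generate_session()` is first-class, tested code, not a fixture. It
emulates:

- **baseline pupil**: an exactly discretized Ornstein–Uhlenbeck process,
  time constant 40 s, stationary SD 6 (% units), mean 50. Mean reversion
  is the very confound the correction module removes, so the generator
  must produce it; the OU process is the simplest stationary Gaussian
  process with an exponential autocorrelation and its conditional-mean
  decay is available in closed form for oracle tests.
- **evoked responses**: difference-of-exponential kernels (rise 1.5 s,
  decay 6 s, peaking ≈ 5 s post-onset for the standard class; rise 4 s,
  decay 15 s for the slower low-luminance responses; a fast variant for
  calcium), scaled by surface amplitudes with multiplicative log-normal
  trial noise (sdlog 0.4, mean 1). The default surfaces are reduced
  (charge-based) with pupil half-max 0.15 μC, calcium 0.062 μC, walking
  0.17 μC, rate midpoint 9 Hz, shapes $b = 2$.
- **noise scale**: the OU baseline induces an additive scalar SD of ≈ 3.4
  (% units) on the windowed evoked measure; together with the
  multiplicative noise this puts the variance explained by the surface
  near 25%, the scale a well-powered pupillometry study reports. The
  trial-level sampler (`sample_evoked_amplitudes()`) adds that same 3.4
  explicitly so recovery studies can run without simulating hours of
  time series.
- **coupling** (imaging sessions): $Ca = aN + \varepsilon$,
  $P = c'N + b\,Ca + \varepsilon$ with $a = 1$, $b = 0.5$, $c' = 0.5$ —
  half of the engagement effect on the pupil runs through the mediator,
  so the true proportion mediated is 0.5.
- **walking**: per-train Bernoulli draws from the walk surface, a
  0.35 cm/s bout during the train decaying with τ = 3 s afterwards, plus
  sparse spontaneous bouts; **blinks** as Poisson missing spans
  (2 per minute, ~0.3 s); **eye position** as fast OU noise, plus a
  train-rate sinusoid when the animal is grounded (the phase-locked-power
  control); **electronics**: measured current = intended × (1 − leak) ×
  sigmoidal width filter (leak 0.1, filter midpoint 0.12 ms).

What it does **not** emulate: pupillary light reflexes and luminance
coupling, saccade kinematics, foreshortening of the pupil ellipse, real
imaging noise statistics (photon shot noise, motion), circuit-level
dynamics of NTS/LC/basal forebrain, or any non-stationarity beyond the
calcium bleach line. Passing tests therefore demonstrate that the
*estimators* are correct and calibrated under the assumed statistical
structure — not that real recordings satisfy that structure.

An optional inverted-U modulation of evoked amplitude by baseline state
(`baseline_mod`, off by default) exists to exercise the sequential
polynomial analysis, which orthogonalizes $[1, X, X^2]$ by QR, tests each
increment with an F statistic whose denominator is the maximal-order
model's mean square (identical to R's sequential `anova(lm(...))`
convention — that equivalence is the oracle test), and reports BIC
$n\ln(SS/n) + k\ln n$ per order with the ΔBIC ≥ 10 rule; additive
constants cancel in the differences.

## Cluster test and spectral quantification

The pixelwise calcium test computes a per-pixel one-sample t over trials,
forms 4-connected clusters of pixels exceeding the two-sided p < 0.05
threshold (the cluster-forming threshold is a choice the correction level
does not pin down; it is exposed as `pixel_alpha`), scores clusters by
summed t with positive and negative excursions kept separate, and builds
the null from per-trial sign flips (cluster p = (1 + #null ≥ obs)/(1 +
n_perm); default 10000 permutations, cluster threshold p < 0.01).
Zero-variance pixels carry no evidence and are excluded. The only
compiled code in the package is the connected-component labelling
(`src/clusters.cpp`), which sits in the permutation loop.

Phase-locked eye-movement power uses a 1 s Hanning window with 0.25 s
hops, power averaged over trials, expressed per frequency as percent
change against the −5.5 to −0.5 s baseline, and summarized at the
frequency bin nearest the train rate over the 10 s train.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
make each statistical claim measurable in minutes on one CPU: 2700-trial
dose-response studies (45 × 60, the full design), 100-seed recovery and
mediation replicate studies, 4–6 full synthetic sessions for the
time-series path (at a 50 Hz native rate), 200-seed null calibrations of
the cluster test at 64 × 64 pixels with 1000 permutations, and 400-seed
null calibrations of the binwise FDR family. Every stochastic step takes
an explicit seed; the pipeline is byte-deterministic given
`vns_config()$seed`, and seeded helpers restore the caller's RNG state so
package calls never perturb a user's random stream.

## Known limitations

- The half-maximal charge of a shallow (b ≈ 2) charge sigmoid is an
  intrinsically noisy estimand: at 2700 trials and realistic (≈ 25%
  variance-explained) noise its sampling SD is roughly 7–13% of its
  value, so single-study estimates should always be read with their
  bootstrap SD.
- Paired binwise tests pair trials by within-cell position after sorting
  by onset, truncating to the smaller cell; with unequal cell sizes this
  discards trials.
- The engagement predictor inherits any misspecification of the surface;
  with 95% training overlap between folds, chance cell-level patterns
  are shared across folds, so "out-of-fold" does not mean independent
  replications.
- The bundle format is a package convention (CSV/JSON, documented in
  `read_session_bundle()`), not an acquisition standard; no NWB/HDF5
  ingestion and no video processing — the pipeline starts from
  ellipse-derived time series.
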