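---
title: "Population attention axes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population attention axes: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In visual cortex, attending to a stimulus inside a neural population's
receptive field (RF) raises stimulus-evoked firing rates by roughly 5-30%.
Whether the *anticipatory* state before a stimulus arrives is just a weaker
copy of that gain — the "stimulation-invariant gain" account — or a
qualitatively different population pattern is a substantive question: a
mixture of anticipatory increases *and* decreases would let a downstream
linear readout separate internal modulatory signals from genuine sensory
drive.

`attnaxes` implements the population-level machinery needed to ask that
question of spiking data from a block-cued two-location change-detection
task, and bundles a session simulator with the statistical structure the
analyses assume, so the entire pipeline is testable without recordings.

## The analysis pipeline

### Attention axes

An *attention axis* is the line in population activity space (one
coordinate per unit) connecting the trial-averaged spike-count vectors of
the two cue conditions. Two axes are estimated from intervals immediately
preceding validly cued, correctly detected targets:

* the **post-stimulus axis**, from spike counts 200-400 ms after the onset
  of the sample stimulus preceding the target;
* the **pre-stimulus axis**, from counts in the 200 ms immediately before
  target onset, then orthogonalized against the (fixed) post-stimulus axis
  by a Gram-Schmidt step.

The orthogonalization is the load-bearing constraint: any behavioral or
predictive signal carried by the pre-stimulus axis is then linearly
independent of the stimulus-evoked attention pattern, which a pure gain
model cannot produce.

Estimation uses repeated random half-splits (default 1000 folds,
stratified by cue condition). Within each fold both axes are fit on the
training half, and all projections are affinely mapped so the training
condition means are exactly +1 (cue in RF) and −1 (cue away). Each
interval's reported projection is its average over folds in which it was
held out; intervals never eligible for training (misses, invalid targets,
sample flashes) are projected in every fold. Held-out averages are *not*
constrained to ±1 — their shrinkage toward 0 is informative.

### Behavior linkage

Target-preceding projections are binned into quintiles per axis, giving a
5×5 map of hit rates (normalized by the session's overall hit rate).
Marginals isolate each axis's unique contribution; Spearman rank
correlations between quintile index and hit rate are Fisher-z averaged
across sessions and tested with one-sample and paired t-tests. Behavioral
sensitivity is summarized with d′ (inverse-normal difference of hit and
false-alarm rates, log-linear correction when a rate is 0 or 1).

### Two-step VAF regression

Each eligible sample flash (preceded by another sample on the same trial)
is reduced to a one-dimensional time series by projecting its smoothed
population activity onto a *stimulus-response axis* (baseline point to the
farthest point of the trial-averaged trajectory). At every millisecond the
centered responses are regressed first onto the post-stimulus projection
of the *preceding* stimulus (scalar least squares; proportion of variance
accounted for, VAF), then the residual onto the pre-stimulus projection of
the immediately preceding inter-stimulus interval. Under independence the
expected VAF is 1/(n−1); a trial-shuffled control verifies this level.
Per-time t-tests against the null level are corrected for multiple
comparisons by requiring a minimum run of consecutive significant time
points, calibrated by simulating autocorrelation-matched (AR(1) by
default) null experiments.

## The synthetic-data generator

`generate_session()` emulates the study conditions end to end:

* **Task**: 400 ms flashes, 300-500 ms fixation and inter-stimulus
  intervals, per-flash target hazard 0.3 (uniform hazard), 90% cue
  validity, |Δθ| ∈ {1, 3, 6, 15}° for valid targets and 3° for invalid,
  blocks alternating cue side after 80 hits with an initial unilateral cue
  phase of 5 hits.
* **Population**: 40 units by default, log-normal baseline rates
  (median 8 spikes/s), a transient+sustained PSTH template (Gaussian
  transient at 60 ms, SD 15 ms, amplitude 2× baseline; sustained plateau
  1× baseline from 40 ms).
* **Attention structure**: per-unit post-stimulus gains `g` with mean 1.09
  and SD 0.15, mixed-sign pre-stimulus modulations `m` with mean 0 and SD
  0.15, correlated with `g − 1` at Pearson 0.46 (bivariate normal — the
  Gaussian copula reduces to this for normal marginals — with clamping to
  keep rates positive).
* **Latent state**: a per-trial AR(1) attention state around ±`state_mean`
  by cue side (persistence 0.7, SD 0.3), plus fast independent
  per-interval noise (SD 0.35), squashed to `u = (1 + tanh(state))/2`.
  During inter-stimulus intervals each unit's baseline is scaled by
  `1 + m·u`; during stimuli the baseline and sustained components are
  scaled by `1 + (g − 1)·u`, and the onset transient carries the
  pre-stimulus pattern `1 + m·u` (controlled by
  `transient_state_coupling`). This makes anticipatory states leave a
  signature on the earliest response — the mechanism whose recovery the
  VAF analysis tests — while the sustained gain reproduces the classical
  post-stimulus effect.
* **Behavior**: hit probability is logistic in `log2 |Δθ|` and in the
  signed attention-toward-target state (slope 1.5); false alarms occur
  per non-target flash at a small state-dependent rate (~1%); response
  times are shifted log-normal with a mild attention speed-up.

`state_mean = 1.25` keeps the squashed state near (but not at) its bounds,
so measured relative attention effects are mildly attenuated relative to
`g − 1`; with the defaults the mean measured post-stimulus effect is about
+7-8%, in the range reported for this kind of task.

The spike process is an exact inhomogeneous Poisson sampler: each unit's
rate is a three-component mixture (baseline, `m`-pattern, gain-pattern
envelopes); spike times are drawn per component by inverse-CDF sampling
and components with negative coefficients are handled by thinning. This is
distributionally identical to per-millisecond Poisson draws but touches
only actual spikes.

### What the generator does not emulate

Real recordings contain correlated (non-Poisson) count variability,
unit-identity turnover, eye-movement artifacts, adaptation across a
session, and tuning-dependent attention effects. Passing tests therefore
show that the *analysis machinery* is correct and well calibrated under
the stated model, not that any particular cortical claim is true of new
data.

## Numerical and design choices

* Epoch windows are half-open `[start, end)` ms relative to flash onset
  (pre: [−200, 0); post: [200, 400); baseline: [−100, 0)), so abutting
  epochs never double-count a spike. Spike times and onsets are integer
  milliseconds.
* The smoothing kernel is a causal half-Gaussian (σ = 20 ms) truncated at
  4σ and renormalized to unit mass (<0.01% mass loss); output before the
  first spike is exactly zero.
* The visual-responsiveness screen slides 50 ms windows in 10 ms steps
  over [0, 400); the paired t-tests per window are uncorrected by design,
  and the type-I behavior of the window scheme is documented by test.
* The blockwise stability CV uses the sample (n−1) standard deviation.
* Degenerate cross-validation folds (raw pre-axis within 1° of the post
  axis) are resampled, up to 20 attempts, with a warning counter; at the
  operating point the raw angle is typically 70-90°, so this guard is far
  from active.
* Axis vectors are unit-normalized before projection; the per-fold affine
  normalization makes downstream results invariant to that choice.
* Quintile ties are broken by stable first-occurrence ranking; perfect
  rank correlations are clipped at |r| = 1 − 1e−10 before the Fisher
  transform. The Spearman correlation pairs the chosen axis's quintile
  index with hit rate across all defined cells of the 25; when every rho
  clips to 1 the cross-session t-test is undefined and reported as NA.
* Regression predictors are mean-centered per session (the response is
  centered by construction), matching the no-intercept scalar form of the
  regression steps.
* The run-length null simulation uses one-sided per-time t-tests (VAF
  above chance), AR order 1 by default with a configurable order, and a
  stationarity fall-back.
* The coupled-pair demonstration model accepts any coupling function, not
  only monotone ones: with a strictly monotone coupling the sign of the
  coupled neuron's attention effect cannot differ between epochs (the
  derivative's sign is fixed), so the epoch-dependent sign flip is
  demonstrated with a unimodal (rise-then-decline) coupling.

## Problem sizes used in the test-suite

The statistical tests run on deliberately reduced problem sizes chosen as
the smallest adequately powered designs: sessions of 25-40 units with 12-80
hits per block, 5-200 cross-validation folds, replicate counts of 10-20
for proportion-of-replicates checks, and a single large 4-block session
for pattern-recovery checks. The full-scale defaults (47 sessions, 1000
folds, 80 hits per block) remain the package defaults for real use.

Two power-related notes. The pre/post effect-correlation recovery check
uses full-size sessions because per-unit estimation noise attenuates a
sample correlation toward zero; at full size the attenuation is a few
percent. The hit/miss projection power check runs at a strong behavior-link
slope (`behavior_attention_slope = 4`), the stated effect size for that
property: at the default slope of 1.5 the one-tailed paired test across 20
sessions has roughly 40-60% per-axis power — anticipatory attention
signals in single-interval projections are intrinsically noisy, and
marginal significance at realistic effect sizes is the expected operating
regime, not a defect.

## Known limitations

* Single global RNG stream: reproducibility is per-run (seed), not
  per-stage.
* The 5×5 Spearman pairing uses the 25-cell variant; the 5-bin marginal
  variant is available through `marginal_performance()` but is not the
  default pairing.
* `d'` uses all completed non-target flashes as false-alarm opportunities;
  per-trial alternatives would change its scale but not the ordering of
  conditions.
* The generator's false-alarm mechanism is phenomenological (logistic in
  the latent state) and only exists so that d′ and trial truncation are
  well defined.
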