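---
title: "Methods: from raw fluorescence to reward-expectation and identity codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw fluorescence to reward-expectation and identity codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design this package analyzes

A head-fixed mouse performs a Go/NoGo social discrimination task: on each
trial an interaction window opens (`O`), taking about 0.4 s to open fully; a
grace period of 0.8–1.3 s follows during which licks have no consequence;
the response window then runs until the window closes 4 s after opening
(`C`). Licking in the response window is rewarded when the presented
stimulus mouse is the reward-associated one (hit) and unrewarded otherwise
(false alarm); withholding is a miss or a correct rejection. Trials repeat
every 12 s, and dorsal CA1 is imaged with a two-photon microscope at
30 frames/s from 1.2 s before `O` to 0.8 s after `C` — 180 frames per trial
at the default timing (`task_spec()`, `epoch_frames()`).

The scientific question is what single neurons and the population encode:
the *expected outcome* (a reward-expectation code that follows the
contingency when stimulus–reward assignments are reversed between days) or
the *identity* of the stimulus mouse (a code that stays with the individual
and therefore flips its Go/NoGo preference under reversal). Everything in
the package serves that dissociation.

# Behavioral scoring and high-performance periods

Outcomes are a pure function of response-window licks
(`score_trials()`): the window is half-open, `[t_response, t_close)`, so a
lick exactly at closing does not count; grace-period licks never count. Hit
rate is hits / reward trials, CR rate is CRs / no-reward trials, correct
rate is (hits + CRs) / trials (`compute_rates()`). High-performance periods
are the union of all 50-trial sliding windows (stride 1) whose hit *and* CR
rates strictly exceed 0.8; a session qualifies when strictly more than 200
trials are covered (`find_high_performance()`). Stride 1 is the
maximal-information reading of a "sliding window" and is configurable; the
strict inequalities are read literally from the rule. All calcium analyses
default to correct trials inside high-performance periods
(`analysis_trials()`).

# Preprocessing: from raw F to calcium-event traces

Per neuron (`preprocess_session()`):

1. **Median filter, order 3, per trial** (`stats::runmed`, edge samples
   kept), then trials are concatenated in order.
2. **Drift correction**: subtract the running 5th percentile in a centered
   900-frame (30 s) window, truncated at the trace edges. The running
   quantile is computed exactly (type-7 definition) by a small C++ routine
   that maintains a sorted window buffer; no approximation or decimation.
3. **Baseline F0**: the mode of a Gaussian kernel density estimate of the
   whole conditioned trace (Silverman's rule-of-thumb bandwidth, 512-point
   grid spanning the data range). The mode is robust to the positive skew
   that transients impose; if drift correction leaves F0 at or below zero,
   the neuron's global 5th percentile is added back and the baseline
   re-estimated (flagged in `baseline_restored`).
4. **dF/F0** = (F − F0) / F0.
5. **Two-pass event threshold** (`detect_events()`): the
   "three-interquartile" value of the pooled pre-opening dF/F0 is computed
   over all trials; trials containing any pre-opening value above it are
   excluded as containing real calcium activity; the value is recomputed
   from the remaining trials and applied to the whole trace. The event
   trace keeps dF/F0 above threshold and is zero elsewhere. Excluded
   trials are removed *only* from threshold estimation, never from
   analysis.
6. **False-positive ratio**: contiguous excursions below −T divided by
   excursions above +T; symmetric noise gives a ratio near 1, a
   transient-dominated trace a ratio near 0. On matched synthetic data the
   median ratio sits well below 5%.

**"Three-interquartile value".** The default reading is median + 3 × IQR of
the pooled pre-opening dF/F0 — a robust z of about 4 for Gaussian noise.
Because the pre-opening dF/F0 is nearly zero-median, the plain 3 × IQR
reading nearly coincides; both it and Q3 + 3 × IQR are available through
`threshold_mode`, so the choice is exposed rather than hidden.

Whether the 900-frame percentile window is centered or trailing is not
determined by the procedure's description; we use a centered window, which
keeps the correction phase-neutral around transients.

# Single-neuron statistics

**Response classification** (`classify_response()`): per trial, the area
under the event trace in the pre-stimulus period (trial start to `O`) is
compared with the stimulus period (opening-complete to response start)
by a paired two-sided Wilcoxon signed-rank test; activated / inhibited /
non-responsive at p < 0.05. The direction is the median of the *nonzero*
paired differences: event traces are sparse, most paired differences are
exactly zero, and the signed-rank test itself discards zeros — the raw
median would otherwise report no direction for plainly modulated neurons.
The response score sums +1/−1/0 codes over the Go and NoGo trial types
(range −2..2; a score of 1 is a neuron activated in Go but not NoGo
trials).

**Discriminability** (`dprime()`): d′ = (μ₁ − μ₂) / √((σ₁² + σ₂²)/2) over
per-trial response amplitudes, where the amplitude is the mean event-trace
value in the analysis window — `O`→response-start for Go/NoGo
discrimination, `O`→`C` for identity discrimination. The sample (n−1)
standard deviation is the default (population form available); raw dF/F0
amplitudes are available as a sensitivity switch.

**Permutation test** (`permutation_test()`): 1000 label shuffles preserving
per-condition trial counts; significant when the observed d′ strictly
exceeds the empirical 97.5th (or falls strictly below the 2.5th) null
percentile, Bonferroni-corrected when several comparisons are made per
neuron (the 6 stimulus pairs of the passive four-mouse condition). Ties
break conservatively; a degenerate null is never significant. Five percent
of null neurons are expected to pass by chance, and the calibration
utility `calibrate_dprime_test()` verifies this empirically.

# Reversal classification and contingency inference

Across a contingency-reversed day pair, registered neurons keeping a
significant Go (NoGo) preference are reward-selective (no-reward-
selective); neurons whose preference flips have preserved their stimulus
tuning and are mouse-selective (`classify_across_reversal()`). Day 1 is
always the earlier session: the analysis follows day-1 selective neurons
forward. Inference uses the 3×3 contingency table of day-1 by day-2 labels:
a chi-square independence test without continuity correction (standard for
3×3 tables; expected counts below 5 trigger a warning), Haberman adjusted
residuals `(O − E)/√(E(1 − r)(1 − c))` — the residual form is not printed
in the source description, so the standard one is used — and four planned
cells (maintained and reversed preferences) tested two-sided at the
Bonferroni criterion p < 0.0125. `stability_analysis()` reports stable and
reversed fractions of day-1 selective neurons against the day-2 base rates
as chance levels.

# Population decoding

`decode_timecourse()` fits an independent linear SVM (C = 1, the fitting
routine's conventional default, exposed in `decoder_spec()`) at every frame
in a leave-one-trial-out procedure. Features are the per-neuron event-trace
values at that frame (dF/F0 optional), standardized with statistics from
the training fold only — the "standardization option" of the original
fitting routine does not specify fold scoping, and training-fold scoping
avoids leakage. Trials are first down-sampled to equal label counts
(`balance_trials()`), once per session, so the trial set is constant across
the time course. A fold whose features all have zero training variance
predicts the majority training label (ties random under the decoder seed).

Multiclass identity decoding (`multiclass_decode()`) trains one-vs-rest
binary classifiers and takes the class with the largest decision value
(winner takes all, chance 1/k; exact ties go to the lowest label index).
Cross-day decoding (`crossday_decode()`) trains on every trial of one
session and tests on every trial of the other, restricted to neurons
registered on both days, and reports the mean signed deviation from chance
over the stimulus epoch plus a label-shuffle band.

**Cluster-based permutation test** (`cluster_permutation_test()`): labels
are shuffled `n_perm` times and the full accuracy course recomputed; each
frame's cluster-forming threshold is the pointwise 97.5th (2.5th)
percentile of the pooled observed-plus-permuted courses — pooling keeps
the observed course exchangeable with the permutations, so the Monte Carlo
p-values are exact under the null; contiguous suprathreshold frames form
clusters scored by the summed deviation from chance (the summed-exceedance
statistic; the cluster statistic is not printed in the source description
and is configurable in principle through the threshold quantile); a
cluster's p-value is the fraction of permutations whose own maximal
cluster score reaches it, both directions pooled, with the usual +1
correction. `calibrate_cluster_test()` measures the realized family-wise
error on null sessions; it sits at the nominal 5%, so any single
100-session estimate still carries binomial noise of about ±2 percentage
points. One deliberate implementation choice: observed and
permuted courses both run through libsvm's internal C-level leave-one-out
cross-validation with globally standardized features. The permutation
comparison is exact because both sides use the identical decoder; the
R-level fold loop with training-fold standardization would make the
100-session calibration run orders of magnitude slower while changing the
accuracy estimates by at most a few points (the two paths are compared
directly in the test suite).

# The synthetic-session generator

The generator plants known ground truth so every stage is validated by
recovery rather than by eyeballing:

- **Schedule**: per-trial rejection sampling under the two presentation
  constraints (no stimulus more than 3 trials in a row; accumulated counts
  of any two stimuli never differing by more than 10). The constraint set
  is never infeasible for ≥ 2 stimuli.
- **Agent**: a logistic acquisition curve interpolates lick probabilities
  from 0.5/0.5 (naive) to 0.95 hit / 0.05 false-alarm asymptotes
  (trained values chosen so a trained agent robustly satisfies the
  high-performance criterion). First-lick latency is normal (0.35 ± 0.15 s
  after the response-window start, truncated at zero) followed by a 7 Hz
  lick bout. Supplying a stale category map simulates the first session
  after a reversal, with below-chance initial performance.
- **Fluorescence**: baseline (100 ± 10 a.u.) + slow sinusoidal drift
  (5 a.u. peak-to-trough over 120 s) + Poisson-timed transients convolved
  with a double-exponential kernel (50 ms rise, 600 ms decay —
  GCaMP6f-like, spanning several frames at 30 Hz) + white noise (sd 2).
  Background transients (0.3 per trial, 0.5 dF/F0) occur everywhere;
  activated neurons add events (default 2 per trial at 1.0 dF/F0) in the
  stimulus epoch of their preferred trials — opening-complete→response for
  reward/no-reward classes, opening-complete→closing for identity classes.
  Inhibited neurons carry a *sparse* tonic event rate (1.5 per trial) that
  is reduced in the preferred epoch: suppression is only observable
  against ongoing activity, and the tonic rate must stay sparse because a
  dense rate floods the pre-opening window and inflates the event
  threshold, making the planted suppression undetectable by construction.
  Reward delivery is a timestamp only; an optional flag adds a post-reward
  lick artifact for robustness testing.
- **Multi-day series** (`generate_multiday()`): reward/no-reward neurons
  are tuned to the trial *type*, so reversing the contingency flips their
  preferred stimulus while preserving their Go/NoGo-epoch modulation;
  identity neurons keep their stimulus. Neurons planted unstable are
  re-tuned to a random class each subsequent day — there is no
  quantitative drift model to inherit, so the stable fraction is a free
  parameter rather than an asserted value. Each day's neurons appear in a
  day-specific order and a registration map links local indices, emulating
  cross-day cell registration output (the registration algorithm itself is
  out of scope; its output is consumed, not produced).

What the generator does *not* emulate: neuropil contamination, motion
artifacts, spike-to-calcium nonlinearity, correlated noise across neurons,
and reward-consumption motor signals (unless enabled). Passing recovery
tests therefore demonstrate the correctness of the analysis logic under
the stated generative model, not robustness to every artifact of real
imaging data.

# Seeds and determinism

A single global seed is split into per-component child seeds by
`child_seed(seed, tag)` (a documented string-hash mix kept inside 32-bit
integer range), so any stage is reproducible in isolation and the whole
pipeline (`run_pipeline()`) is a pure function of (config, seed). All
seeded draws run in a local RNG scope and never disturb the caller's RNG
stream.

# Problem sizes used in the shipped checks

The calibration and recovery runs are sized to be informative at desk
scale; each size is a package choice stated here:

- permutation-test calibration: 2000 null neurons × (100 + 100) trials ×
  1000 shuffles;
- multiclass chance calibration: 20 noise neurons, 60 balanced trials per
  stimulus mouse, every 12th frame (0.4 s spacing) of the
  opening-to-closing epoch;
- reversal parameter recovery: 200 neurons (20 reward, 10 no-reward, 20
  identity, 150 non-responsive), 300 trials/day, one reversed day pair;
- drift dissociation: 30 neurons (16 identity-coding), 80 trials/day, two
  same-contingency days, planted stability 100% versus 0%;
- cluster-test calibration: 100 null sessions, 200-permutation inner loop,
  20 trials × 10 neurons × 8 decoded frames each.

# Known limitations

- The response-score codebook beyond the quoted anchor cases is inferred
  as the −2..+2 sum of per-type codes.
- With unequal pre-stimulus (1.2 s) and stimulus (0.9 s at the default
  grace) windows, the area comparison is asymmetric for tonically active
  neurons; this mirrors the stated procedure and is mitigated by the
  sparse event traces.
- The passive-condition significance uses the mean-|d′| statistic over the
  6 pairs with the upper permutation tail at the Bonferroni-corrected
  level, a concrete reading of "averaged d′ with correction" that is
  exposed in code.
- Leave-one-out decoding of truly uninformative data is slightly
  pessimistic (the held-out trial's class is under-represented in
  training), so null decoding accuracy sits a point or two below nominal
  chance; the calibration utilities quantify this.
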