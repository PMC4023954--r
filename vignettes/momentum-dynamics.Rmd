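---
title: "Analyzing team dynamics under manipulated momentum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing team dynamics under manipulated momentum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentumdyn)
```

## The experimental design this package models

`momentumdyn` analyzes dyadic rowing-ergometer sessions in which a displayed
race against a virtual opponent is manipulated to induce *positive momentum*
(the team steadily gains on the opponent) or *negative momentum* (it steadily
falls behind). The displayed time gap — the seconds between the two boats,
signed from the team's perspective — is the scaled control parameter. A
session has three phases:

* a **priming phase** (default 3.20 min) ending at the momentum starting gap
  (−6 s for positive momentum, +6 s for negative),
* a **momentum phase** (default 6.40 min) in which the gap steps by 2 s
  across **seven equal-duration sections**, from ∓6 s to ±6 s,
* a **completion phase** (default 1 min) holding a final gap strictly inside
  ±8 s (no full victory or defeat), excluded from analysis.

The momentum phase is described as a 2 s change "each minute", which cannot
tile a 6.40-min phase with seven distinct gap values; we therefore divide the
phase into seven equal sections of 6.40/7 min ≈ 54.9 s. All durations are
configurable, and none of the downstream statistics depend on the exact
in-race step times — they operate on section summaries. Similarly, the phase
durations sum to a 10.60-min session; a session can be made longer via the
completion duration, but the analyzed momentum phase is unaffected.

Four variables are tracked per team: **collective efficacy** and **task
cohesion** (one 9-point item each, answered by both rowers once per section;
the team score is the two rowers' mean), **exerted effort** (handle force in
newtons at 100 Hz, averaged over the two rowers), and **interpersonal
coordination** (the continuous relative phase between the two rowers' handle
trajectories, in degrees, and its standard deviation).

## Continuous relative phase

Each rower's handle position (calibrated from camera pixels to centimeters)
is low-pass filtered and standardized, and the instantaneous phase
$\varphi_i(t)$ is the argument of the analytic signal — the complex series
whose real part is the standardized position $s_i(t)$ and whose imaginary
part is its Hilbert transform $H[s_i](t)$:

$$\varphi(t) = \varphi_1(t) - \varphi_2(t), \qquad
  \varphi_i(t) = \arg\!\big(s_i(t) + i\,H[s_i](t)\big),$$

wrapped to (−180°, 180°]. $\varphi = 0$ means perfect in-phase coordination;
SD$\varphi$ over a section indexes the *stability* of coordination (lower =
more stable). Numerical choices:

* **Filter**: 2nd-order Butterworth, 4 Hz cut-off, applied forward and
  backward so the net phase shift is zero — one-directional filtering would
  bias $\varphi$ by the filter's group delay. Order and cut-off are
  arguments. The forward-backward pass is wrapped in odd-reflection padding
  so start/end transients do not leak into the record.
* **Sign convention**: $\varphi = \varphi_1 - \varphi_2$, so if rower 2 lags
  rower 1 by $\delta$ degrees the relative phase is $+\delta$. The
  convention is arbitrary but fixed and tested via antisymmetry.
* **Edge trim**: analytic-signal phase estimates are unreliable at record
  edges; 5% of samples at each end (configurable) are flagged and excluded
  from section summaries. At the default durations the flagged samples fall
  inside the priming and completion phases, which are excluded anyway.
* **Wrapped, signed summaries**: section means and SDs are ordinary (linear)
  statistics of the wrapped series. In the small-angle regime these data
  occupy (single-digit degrees) linear and circular statistics coincide; a
  circular SD is available via `circular_sd = TRUE`, and the mean absolute
  phase (`mean_abs_phi`) is reported alongside the signed mean because
  published tables do not state which of the two they print.
* **Degenerate inputs**: constant (zero-variance) channels are rejected at
  standardization — phase is undefined for them — and series shorter than
  the filter warm-up are rejected by name.

## The synthetic cohort

No raw data from the original experiment are public, so the package ships a
generator (`generator_config()`, `generate_cohort()`) that emulates the
study's structure: per team, one positive and one negative session of two
coupled kinematic channels (100 Hz, cm), two force channels (100 Hz, N) and
7 × 2 integer item responses per rower.

* **Kinematics**: rower 1 follows an asymmetric, band-limited stroke
  waveform $\sin(\theta + 0.3\sin\theta)$ at 0.5 Hz (30 strokes/min, a
  typical ergometer rate) with a 150 cm stroke; rower 2 follows the same
  waveform lagged by a phase offset that wanders smoothly (low-pass
  filtered noise) within each section around the configured per-section
  mean and SD — the SD is what creates section-level differences in
  SD$\varphi$.
* **Force**: squared half-sine pulses locked to each rower's drive, scaled
  so the section mean force follows a per-scenario baseline-plus-slope
  trend times a per-team lognormal power multiplier. Forces are clipped at
  zero newtons.
* **Items**: `round(clip(baseline + slope·(section−1) + noise))` per rower,
  clipped to the 1–9 scale.
* **Team heterogeneity**: the power multiplier and a baseline phase offset
  are drawn once per team — this is exactly the heterogeneity that makes
  within-team (rather than whole-sample) shuffling necessary downstream.
* **Calibration**: raw volt and pixel channels are generated by inverting
  the affine calibrations, so `volts_to_newtons()` / `pixels_to_cm()` are
  exercised end-to-end.

Default trend parameters mirror the published sample table of the original
experiment (efficacy ≈ 4.4 → 7.6 under positive momentum and 7.9 → 3.1 under
negative; force near 145 N declining ~1.7 N/section under positive and ~3.1
under negative; mean relative phase around 5°). Stroke rates and force noise
are not reported there, so those defaults are plausible values for trained
rowers at drag-factor-style workout resistance, not calibrated estimates.
What the generator deliberately does **not** model: flywheel/drag dynamics,
stroke-rate drift, fatigue autocorrelation, giving-up behavior, or any
coupling of item responses to performance. Passing tests therefore show that
the *pipeline* recovers the structure it assumes, not that real rowing data
satisfy those assumptions.

Determinism: every team/session draws from a substream seed derived from the
master seed, so identical configs reproduce bit-identical cohorts and adding
a team never perturbs the others.

## Sectioning and aggregation

`section_slices()` maps the seven momentum segments onto sample indices
(right-open intervals; priming and completion samples are excluded — the
analysis is indexed by the seven gap values). `summarize_session()` produces
the per-section team summaries; `sample_summary()` aggregates across teams
into the published layout, with an `"All"` row whose mean is the arithmetic
mean of the seven per-gap means and whose SD is taken over all team-section
values (the source table does not state its aggregate SD's definition; this
choice is documented output metadata, and with a single team every
across-team SD is reported as missing). Item responses attach to sections by
order — the k-th response pair belongs to the k-th gap period, as the items
were shown shortly after each gap change. Missing responses propagate as
explicit `NA`s, and a team missing any section is excluded (with a warning)
from paired tests, mirroring how incomplete teams were dropped in the
original study.

## Monte Carlo permutation inference

All tests shuffle **within teams** — teams differ in power and baseline
coordination, so they are not one homogeneous sample — and use the add-one
estimator $p = (1 + \#\{|T^\ast| \ge |T_{obs}|\})/(B + 1)$, two-sided, with
a mandatory seed and $B = 5000$ by default.

* **Trend test** (`trend_test`): the statistic is the across-team mean of
  per-team least-squares slopes of the measure on section index 1–7. The
  null permutes each team's seven section values independently. Slope is
  our choice of trend statistic: the source analysis never names one, and
  the slope is the minimal statistic that distinguishes increase from
  decrease over seven ordered sections and supports "steeper" comparisons.
* **Trend-difference test** (`trend_difference_test`): pairs each team's
  two sessions; the null swaps the scenario labels within teams (a sign
  flip over the $2^n$ space). For measures whose expected trends have
  opposite signs the steepness statistic $|b_{neg}| - |b_{pos}|$ is used
  (a plain difference of slopes would be invariant under the label swap
  for exactly opposite trends and is kept as `mode = "plain"` for same-sign
  measures such as force).
* **Pairwise contrasts** (`pairwise_gap_test`): mean within-team difference
  between two cells — adjacent gaps within a scenario (the effort
  "building / cruising / coasting / final kick" profile) or the same gap
  across scenarios — with within-team swaps of the two values as the null.
* **Combined coordination test** (`combined_phase_test`): coordination
  quality is *better when closer to zero* in both the mean relative phase
  and SD$\varphi$, so the two metrics are tested jointly: session-level
  metrics (mean |$\varphi$| and mean SD$\varphi$ across sections) enter
  per-team negative-minus-positive contrasts; one set of within-team label
  swaps is applied jointly to both metrics; per-metric p-hats are computed
  by rank within that joint null and combined with Fisher's
  $-2(\ln \hat p_{\varphi} + \ln \hat p_{SD\varphi})$; the combined p is
  the add-one proportion of permutations whose Fisher statistic reaches the
  observed one. The construction of the original combined p-value is
  unreported; permutation-Fisher is the standard way to combine dependent
  permutation tests, and it is exact under the joint swap null. This test
  is one-sided in the quality direction.

**Effect sizes.** Cohen's d is computed per team — the team's observed
result divided by a pooled SD — and averaged. Which spread enters the pooled
SD is not stated in the source; we use the team's own section SD (pooled
over both sessions for paired tests), and for trend tests the per-team
observed result is the fitted overall change across the momentum phase
(6 × slope) so that d is on the measure's scale. Under a pure noiseless
linear trend this definition caps |d| near 2.8, lower than the largest
published values, which likely used a residual-style spread; since the raw
data are unavailable either way, the definition is fixed, documented, and
exposed (the permutation-null SD can be used instead by dividing the
observed statistic by `null_summary["sd"]`).

No multiple-testing correction is applied (none was in the source); all
p-values are reported together with the number of tests so users can adjust.

## Problem sizes used in validation

The test suite validates closed forms at full scale (100 Hz, 10.6-min
records) and runs replication-heavy checks — type-I-error calibration of all
four test families (500 replicate cohorts at $B = 1000$), power, and
parameter recovery — on reduced cohorts (20 Hz, 5–8 s sections). Section
exchangeability under the null generator holds at any scale, so the reduced
size changes only runtime, not the null being tested. The permutation
machinery itself is checked against exhaustive enumeration (all $(3!)^2$
joint orderings; all $2^n$ sign flips) on toy inputs.

## Known limitations

* The generator's defaults mimic published section means; they are not
  fitted to raw data, and the published inferential statistics (specific
  p-values and d's) are not reproducible without the per-team raw data.
* Linear phase summaries assume the small-angle regime; for dyads with
  large or wrapping relative phase use `circular_sd = TRUE` and
  `mean_abs_phi`.
* The trend statistic is a straight-line slope; genuinely non-monotone
  profiles (the effort dynamics, for instance) are better read from the
  pairwise gap contrasts than from the trend test.
* Item responses are modeled as independent rounded Gaussians; real
  responses are serially correlated within a session.
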