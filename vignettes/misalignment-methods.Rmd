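---
title: "Methods: circadian-misalignment analysis of DAM recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian-misalignment analysis of DAM recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misalignr)
```

This vignette documents the models and procedures implemented in
`misalignr`, the assumptions behind them, the tunable parameters, and the
numerical choices made where the design was genuinely open. The package
analyses Drosophila Activity Monitor (DAM) experiments in which flies live
under either a 24-h LD 12:12 schedule or a chronically misaligning 28-h
LD 14:14 schedule (daily 4-h phase delays) while their per-minute beam-break
counts are recorded until death.

## Data model

Every analysis consumes a dense per-minute, per-fly count series
(`beam_series`): bin *i* covers the minute starting at `origin + (i - 1)`
minutes, and a lifespan or event time of *m* minutes means the last beam
break happened *m* minutes after the origin. Three consequences:

* **Invalid monitor rows** (status codes other than 1) are zero-filled, not
  treated as missing, so downstream sleep and death logic always sees a
  dense series. The alternative — NA propagation — would force every
  statistic to define its own missing-data rule; zero-filling is logged so
  affected minutes can be audited.
* **Weekly tube transfers** split a fly's record across monitor files;
  `concatenate_weeks()` re-joins parts and zero-fills gaps up to 120 min.
  Transfers take minutes, so a larger gap is treated as data loss and
  raises an error rather than silently fabricating a week of inactivity.
* **Weeks** are fixed 168-h blocks from the experiment origin for both
  groups, so "week k" is a calendar unit, not a number of cycles: it holds
  seven 24-h cycles for controls and six 28-h cycles for misaligned flies,
  equalising weekly light exposure (84 h each).

Light schedules use half-open intervals: lights are on for zeitgeber time
ZT in [0, photoperiod) and off for [photoperiod, T). ZT = photoperiod is
therefore dark, and `lights_state()` changes exactly twice per cycle. ZT is
undefined in constant darkness (DD); DD analyses index time from DD onset
instead.

## Death calling and ghost readings

Lifespan is the last minute with a beam break. DAM hardware occasionally
emits a solitary count long after a fly has died; calling death from the raw
maximum would credit such a fly with extra days of life. A nonzero bin is
discarded as a *ghost* iff it is isolated on **both** sides: the nearest
preceding retained nonzero bin is more than 720 min earlier, and the
nearest following nonzero bin is more than 720 min later (or absent). The
scan runs left to right against retained activity, so a cluster of genuine
late-life counts anchors itself: once one count of the cluster is kept, the
rest sit within 12 h of retained activity and are kept too. A one-sided
rule would delete real terminal activity bouts, which is why isolation on
both sides is required. Ghost filtering can only remove counts, so it never
increases a called lifespan, and a series without any 12-h silent gap is
returned unchanged.

## Survival analysis

Kaplan-Meier estimation, the two-group log-rank test and Cox
proportional-hazards fits are delegated to the `survival` package (the
field-standard implementation) behind thin tidy wrappers:

* KM confidence intervals are log-log transformed (Greenwood variance); the
  median is the smallest time with survival at or below 0.5.
* Cox models use the **Efron** tie correction. Lifespans resolve to days in
  practice, so ties are massive and the Breslow approximation would bias
  coefficients toward zero.
* The sleep covariate is expressed in **hours of sleep per day**
  (min/hr x 24/60), so a fitted hazard ratio reads "per additional hour of
  daily sleep".
* A global Schoenfeld-residual test (`survival::cox.zph`) is attached to
  every fit (`glance()$ph_global_p`). Proportional-hazards violations (seen
  in practice for female flies, where the misalignment effect is stronger
  early) are *flagged, not modelled*; time-varying effects are out of
  scope.

Two helpers convert fitted ratios into the quantities usually quoted:
`hazard_percent(h)` = 100(h − 1) rounded half-up, and
`equivalent_sleep_loss(h_t, h_s)` solves `h_s^(-x) = h_t` for the hours of
daily sleep whose loss would match the treatment effect,
x = log(h_t)/(−log(h_s)). All printed-statistic rounding is half-up at the
displayed precision, since R's default banker's rounding can differ in the
last digit.

### Sleep matching

To ask whether misalignment shortens life *beyond* its effect on sleep,
each control fly is paired with a misaligned fly of similar weekly sleep
(within 0.5 min/hr), without replacement. Controls are processed in
ascending sleep order and each takes the *lowest-sleep* unmatched partner
within tolerance (ties broken by fly id). For one-dimensional matching with
a fixed tolerance this leftmost-feasible greedy provably attains the
maximum possible number of pairs, unlike nearest-neighbour greedy, which
can strand a feasible partner (controls {0, 0.4} against candidates
{−0.5, 0.4} pair twice under our rule but once under nearest-neighbour).
Determinism and maximality were preferred because the matched-cohort hazard
ratio depends on which flies survive the matching.

## Sleep scoring and summaries

Fly sleep is >= 5 consecutive minutes without a beam break; every maximal
zero run of length >= 5 is a bout and all of its minutes are sleep. Scoring
truncates at called death — post-mortem minutes are neither sleep nor wake —
so a dead fly cannot drift into "60 min/hr sleep".

Weekly summaries include only flies that survived the entire week, and
divide by the fixed 168-h week (not alive-hours, which are equal for
included flies by construction). Full-life summaries exclude the final
three days of life, where moribund inactivity is indistinguishable from
sleep, and require a lifespan above 72 h.

Activity and sleep profiles fold each fly's week onto a 30-min ZT grid (2T
bins per cycle: 48 for T = 24, 56 for T = 28) across the week's complete
cycles, then average across flies with SEM across flies (matching how such
profiles are reported, with n = flies). The weighted mean of a fly's bin
means equals its overall rate, a conservation property the tests enforce.
Actograms use per-fly mean normalization over the plotted window — each
fly's counts divided by its window mean — so vigorous flies do not dominate
the average; the result is laid out in 24-h rows for single plotting.

Sleep-longevity association uses Spearman's rank correlation with a
Fisher-z 95% interval (se = 1/sqrt(n − 3)); ranks make the statistic robust
to the heavy right skew of lifespan.

## Chi-squared periodogram

For trial period P (1-min steps) the N-bin series is folded into P columns;
with column means M_h, grand mean M and overall variance s², the statistic
is

    Q(P) = K * sum_h (M_h − M)² / s²,   K = N / P,

which is approximately chi²(P − 1) under arrhythmia because each column
mean carries variance s²/K. The significance line is the chi² quantile at
1 − alpha (default alpha = 0.01); **rhythm power** is Q at the dominant
period minus that line, and a fly is rhythmic iff power > 0. Numerical
choices:

* The **dominant period** is the argmax of Q *relative to the significance
  line*. The null level of Q grows like P − 1, so the raw-Q argmax over a
  wide range (the default 16-36 h brackets both 24-h and 28-h entrainment)
  drifts to the long edge — and onto the 1.5xT subharmonic ridge of
  24-h rhythms at 36 h — for moderately rhythmic flies. Subtracting the
  line removes the degrees-of-freedom tilt; ties take the smallest P.
* An incomplete final fold column is averaged over however many rows cover
  it; truncating to complete cycles would discard up to one cycle of data.
* Q is scale-invariant (multiplying all counts by a constant changes
  nothing), constant series are rejected (zero variance), and the series
  must span at least two cycles of the longest trial period.
* DD analyses exclude the first 24 h after transfer into darkness (transfer
  disturbs behaviour) and require >= 6 analysable days; the default DD
  search range is 18-31 h around the ~24-h free-running period.

Exact numerical parity with closed-source periodogram software is not
claimed; the test surface is an independent naive fold-and-average oracle,
which the implementation must match to 1e-9 relative.

## DE cross-classification

Given per-gene (log2FC, BH-adjusted p) tables for the misalignment contrast
and an aging contrast, each gene receives exactly one label:
`not_ccm_significant` (CCM padj >= 0.1); `convergent` (same sign, aging
padj < 0.1); `trend_same` (same sign, 0.1 <= aging padj < 0.3); `opposite`
(opposite sign, aging padj < 0.3); else `unclassified` (including missing
values and zero fold changes, whose direction is undefined and warned
about). All padj intervals are half-open [lower, upper): the sources of
such thresholds rarely state endpoint conventions, and a fixed convention
keeps counts reproducible. The relaxed 0.3 cutoff for opposite regulation
deliberately catches genes that aging leaves unchanged or pushes the other
way — the operational definition of a misalignment-specific change.
Duplicate gene ids (e.g. merged multi-mapping genes from upstream counting)
must be resolved before classification and raise an error naming the
duplicates. Fold-change correlations between contrasts default to Spearman
(Pearson available), with the same Fisher-z interval as above.

The package ships a 16-gene example table (`example_de_table()`) of genes
significantly regulated by misalignment whose aging response runs the other
way; classifying it yields 12 opposite-down and 4 opposite-up genes.

## The synthetic-data generator

`simulate_fly()` emulates the statistical structure the pipeline assumes,
not fly neurobiology:

* **Behaviour**: a two-state (active/rest) Markov chain per minute. The
  stationary rest probability follows the (subjective) day: night rest 0.88,
  baseline day 0.45, midday siesta 0.75 (middle 30% of the photoperiod),
  anticipation windows 0.12 beginning 8.5 h after the previous lighting
  transition, a 1-h activity tail after lights-off, and 10-min startle
  bursts at transitions (rest 0.02, Poisson rate x6). Mean rest-bout length
  grows with rest propensity (5-30 min), so scoreable >= 5-min sleep bouts
  are common at night and rare in anticipation windows. Active minutes emit
  Poisson(2) counts. A Markov chain rather than a pure inhomogeneous
  Poisson process was chosen precisely so that bout structure — what sleep
  scoring measures — is controllable.
* **Aging**: each week the rest-probability modulation and startle
  amplitude shrink toward their cycle mean by a factor 0.85, so rhythm
  power declines with age while mean activity stays comparable.
* **Free-run**: in DD the subjective cycle continues from the phase held at
  the end of the last LD epoch, advancing with an internal period (default
  1440 min, settable, e.g. 1438 min) in place of the external T.
* **Mortality**: Gompertz hazard a·e^{bt} with b = 0.15/day and a chosen so
  the control median is 23 days; misaligned flies' hazard is multiplied by
  e^{log HR} (default HR 1.94). The Gompertz median has a closed form,
  giving an exact oracle for recovery tests, and the proportional-hazards
  effect makes Cox recovery well-posed. When the activity rate is nonzero,
  a final beam break is forced at the drawn death minute so the last-
  activity death call matches the programmed truth exactly.
* **Ghosts**: with probability 0.1 per fly, one count of 1 is placed
  uniformly more than 12 h after death; if the record ends too soon, no
  ghost is placed and a warning is raised.
* **Determinism**: every fly's record is a pure function of its seed;
  cohort seeds derive from hashing (master seed, fly index), so results do
  not depend on simulation order. All random numbers are drawn from R's RNG
  (the C++ kernel only threads the chain state), making records
  bit-reproducible across platforms.

The generator's activity intensities are calibrated to make the package's
statistical properties sharply testable (entrained flies recover their
imposed period to the minute; programmed hazard ratios are recovered within
Monte-Carlo error). They are *not* fitted to any real cohort: passing tests
demonstrates the pipeline's correctness on data satisfying its assumptions,
not that real flies behave like the generator. In particular the generator
omits inter-fly frailty, non-proportional hazards, position effects within
monitors, and activity-dependent mortality.

## Problem sizes and runtime choices

The test suite and acceptance script use cohort sizes chosen to balance
Monte-Carlo precision against runtime: 500 flies per arm for hazard-ratio
recovery (log-HR standard error ~0.06, so the programmed HR 1.94 is
recovered within [1.7, 2.2] and a null cohort within [0.85, 1.18]), 250
ghost-injected flies for death-call integrity, 5 flies per arm for
entrainment recovery (which is deterministic to the minute at default
signal strength), 1000 random days for sleep-scorer oracle parity, and 20
random fixtures for periodogram oracle parity at 1e-9 relative tolerance.

## Known limitations

* Single-beam DAM only; multi-beam or sub-minute variants are out of scope.
* ZT-based profile windows assume whole weeks; the alternative anchoring of
  profile windows at ZT18 is exposed as a window offset rather than a
  default.
* The periodogram reports one dominant period; split rhythms produce a
  single argmax, not two components.
* Sleep-matched cohorts equalise sleep but nothing else; unmeasured
  confounders of the matched comparison are untouched.
* The Fisher-z interval for Spearman's rho is approximate under heavy ties.
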