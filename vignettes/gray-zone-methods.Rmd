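---
title: "Methods: two-threshold calibration of a visual analogue stress scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-threshold calibration of a visual analogue stress scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grayzone)
```

## The problem and the model

A worker-level screening table carries two measurements of perceived
stress: a 0–10 visual analogue scale (VAS, 0.1 resolution) that is quick
enough for routine occupational-medicine visits, and a Perceived Stress
Scale (PSS14) total expressed on the same 0–10 axis, which serves as the
reference. Dichotomising the reference at 7.2 defines a "stressed" class,
and the calibration question is where to cut the VAS.

Every step downstream of that dichotomy treats the VAS as an ordinal test:
a worker tests positive when `vas >= t`. The package computes the
empirical ROC curve over the observed VAS values, the Mann–Whitney AUC
(tie pairs count one half), a DeLong normal-theory interval for the AUC,
and the single optimal cut-point under three standard criteria (Youden's
J, the Se·Sp product, closest-to-(0,1)). The contribution of the pipeline
is what happens next: the single cut-point is deliberately demoted. Two
constructions quantify where it is *unreliable*:

* **Bootstrap of the cut-point.** Resample the cohort with replacement,
  re-estimate the optimal threshold on each replicate, and take the
  percentile interval of the resulting distribution. This measures pure
  sampling instability of the cut-point estimator.
* **TG-ROC inconclusive zone.** Plot monotone continuous estimates of
  Se(t) and Sp(t) against t and mark the interval where *neither* reaches
  a performance goal (0.90). This measures where the test itself cannot
  meet the goal, independent of estimation noise.

The gray zone is the interval hull of the two ("the largest interval"):
its lower end is the at-risk threshold, its upper end the intervention
threshold, and classification is three-valued with both bounds belonging
to the at-risk zone.

The two constructions answer different questions and neither dominates:
with very small positive classes the bootstrap interval is wide and the
TG-ROC zone comparatively stable; as the cohort grows the bootstrap
interval collapses toward a point while the TG-ROC zone converges to a
*population* quantity — the interval between the 10th percentile of the
positive-class VAS distribution and the 90th percentile of the
negative-class distribution — whose width does not vanish. The merged
zone therefore shrinks with n only until the TG-ROC component takes over;
the shrink-with-n property belongs to the bootstrap half, and the test
suite asserts it there (averaged over replicate cohorts, since a single
realization is noisy).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `pss_cutoff` | 7.2 | score (0–10) | reference definition of "stressed"; the analysis is conditional on it |
| `n_boot` | 1000 | replicates | percentile endpoints at 2.5%/97.5% are stable to ~1 grid step at this size |
| `level` | 0.95 | — | conventional, used for DeLong, Wilson and percentile intervals alike |
| `stratified` | `TRUE` | — | with a ~2% positive class, unconditional resampling makes the positive count vary with SD ≈ 3 of 9; fixing prevalence removes that nuisance variance (the unstratified variant is always computed alongside as a robustness check) |
| `goal` | 0.90 | Se/Sp fraction | the customary TG-ROC performance goal; "greater than 0.90" is read strictly, so points with Se or Sp exactly 0.90 stay inconclusive |
| `grid_step` | 0.1 | score | matches the VAS measurement resolution; reporting finer than the instrument would be spurious precision |
| `criterion` | youden, product, closest01 | — | all three are scanned; agreement among them is itself a reported finding |
| `tie` | highest | — | among thresholds attaining the same optimum, the highest favours specificity, consistent with an intervention-oriented reading; configurable |

## The synthetic generator

`generate_cohort()` emulates the reference screening cohort: n = 500,
PSS14 3.8 ± 1.4, VAS 4.0 ± 2.4, Spearman correlation 0.65, prevalence
1.8% at the 7.2 cutoff. The joint model is a Gaussian copula — a latent
bivariate normal with Pearson correlation ρ = 2·sin(π·r_s/6), the identity
that makes the latent Spearman correlation equal the target r_s exactly —
with truncated-normal marginals on [0, 10] and rounding to the 0.1 grid.
Truncated (not clipped) marginals keep the support honest; the config
stores pre-truncation parameters, and truncation to [0, 10] shrinks the
realised moments (for the VAS marginal the population SD is ≈ 2.19 rather
than 2.4; the parameter-recovery tests compare against the closed-form
truncated moments).

Two-moment marginals cannot reproduce both the centre (3.8 ± 1.4) and the
upper tail (1.8% at 7.2) of the PSS14 distribution — the empirical
distribution is right-skewed in a way a normal is not: a truncated normal
with mean 3.8 and SD 1.4 puts only ~0.8% of its mass at or above 7.2.
Because the analysis lives entirely in the tail (the positive class), the
default resolves the conflict in the tail's favour: `calibrate_tail = TRUE`
shifts the PSS14 location so that P(pss14 ≥ 7.2) = 1.8% exactly at the
population level (location ≈ 4.26). Setting `calibrate_tail = FALSE`
recovers the configured centre instead. This choice is fixed once;
demographics (gender, age, education, role, sector) are drawn
independently from the reference cohort's marginal frequencies.

What the generator does **not** emulate: the skewness of the real score
distributions, any dependence between demographics and scores, and any
fine structure of the VAS-given-PSS conditional beyond rank correlation.
Consequences that tests on synthetic cohorts therefore *cannot* establish
about real data: the exact printed cut-point and zone (the emulation
centres the cut-point near 6, slightly below the reference 6.8, and
produces somewhat narrower bootstrap intervals than a skewed empirical
distribution would), and the near-identity of stratified and unstratified
bootstrap intervals, which the tests only require to agree within 1.0.
What they do establish: the correctness of every estimator against
independent oracles, and that under the stated study conditions the
pipeline reproduces the reference analysis's qualitative structure
(high AUC, criterion-independent cut-point, a gray zone bracketing it,
no-follow-up the largest zone) with quantities inside sampling-variability
bands of the published ones.

## Numerical conventions

* **Score tolerance.** All boundary comparisons (`pss14 >= 7.2`,
  `vas >= t`, zone membership) use a 1e-9 tolerance: 0.1 is not exactly
  representable in binary, and 7.2 must include workers recorded as 7.2.
* **Candidate thresholds** are the distinct observed VAS values plus one
  sentinel below the minimum (Se = 1, Sp = 0). Midpoint candidates are
  deliberately not used: they would produce cut-points off the 0.1
  measurement grid.
* **Quantiles.** Medians/IQRs and percentile bootstrap intervals use
  linear interpolation between order statistics (`quantile()` type 7, the
  inclusive spreadsheet convention).
* **Mann–Whitney.** Midranks for ties throughout; above a combined n of 12
  the tie-corrected, continuity-corrected normal approximation (the
  reference group sizes, 491 vs 9, force the approximation); at or below
  12, exhaustive enumeration over all group assignments, which stays exact
  under ties and serves as the oracle path.
* **Se/Sp intervals.** Wilson score by default — it reproduces sensible
  intervals at the tiny positive-class sizes this design produces (8/9
  successes), where the Wald interval fails; Clopper–Pearson is available
  behind `method =`.
* **DeLong CI** is truncated to [0, 1]. A perfectly separated sample has
  zero placement variance and a degenerate interval at 1.
* **TG-ROC smoother.** The contract is continuous, monotone, bounded
  estimates of Se(t) and Sp(t). The default is a Hyman-filtered monotone
  cubic spline through the empirical step points anchored at (Se = 1,
  Sp = 0) below the support and (Se = 0, Sp = 1) above; alternatives are
  the raw right-continuous step curves (`"isotonic"` — right-continuous
  because a cut-point between observed scores classifies exactly like the
  next observed score above it) and plain linear interpolation (`"none"`).
  If the inconclusive set is empty, the zone degenerates to the grid point
  where the two curves cross.
* **Bootstrap degeneracy.** Unstratified replicates that lose an entire
  class have no ROC; they are redrawn (not skipped), keeping exactly
  `n_boot` values, and the redraw count is attached to the result.
  Stratified replicates keep the original class sizes by construction.
* **Merge rule.** Interval hull even for disjoint inputs (with a warning);
  the reference analysis only encountered nested intervals, and the hull
  is the unique choice that preserves "the largest interval" in all cases.
* **Seeds.** `analysis_config(seed =)` derives fixed per-stage seeds
  (stratified bootstrap, unstratified bootstrap) so any stage can be rerun
  in isolation; equal seeds give byte-identical reports, including the
  full stored bootstrap distributions.

## Problem sizes used by the test suite

Oracle comparisons run on toy cohorts of up to 30 workers (where nested
loops and exhaustive enumeration are exact and fast). Distributional
checks use n = 20,000–100,000 single cohorts for copula and tail
calibration, 200 replicate cohorts at n = 500 for parameter recovery, and
bootstrap sizes of 150–1,000. The full acceptance pipeline runs at the
study conditions (n = 500, 1,000 bootstrap replicates, all three criteria,
both resampling schemes) in a few seconds.

## Known limitations

* PSS14 is consumed as an aggregate 0–10 score; item-level scoring and the
  mapping from the conventional 0–56 total to the 0–10 axis are out of
  scope (the reference cut-off 7.2 lives on the 0–10 axis).
* The copula emulation is an assumption, stated as such; it is the
  testbed, not evidence about any particular real cohort.
* With ~9 positives, the positive-class Wilson interval is wide
  (0.57–0.98 at 8/9) and the bootstrap lower endpoint is driven by a
  handful of workers; nothing in the machinery repairs a reference class
  this small, it only propagates the uncertainty honestly.
* The gray zone inherits the reference definition: it cannot be computed
  for the reference instrument itself, and a different `pss_cutoff` yields
  a different zone.
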