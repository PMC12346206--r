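---
title: "Modelling the cost of diabetic hand infections with dhicost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost of diabetic hand infections with dhicost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhicost)
```

## The problem

Hand infections in diabetic patients progress quickly from cellulitis to
deep-space infection, osteomyelitis and amputation, and the resulting
costs — hospitalization, surgery, a year of outpatient follow-up, and lost
work — are substantial but rarely quantified. `dhicost` implements a
complete cost-of-illness workflow for this setting: cohort emulation, cost
aggregation, currency restatement, Monte Carlo uncertainty propagation and
rank-based group comparison. Because the underlying per-patient data of
the calibrating case series are not public, the package treats the
published *marginal* summaries as its calibration targets and makes the
distinction between what is reproduced exactly and what is emulated
explicit throughout.

## The synthetic cohort generator

The generator has two modes.

**Fixture mode** (`build_reference_fixture()`) is fully deterministic — no
random number generation — and reproduces every published marginal count
exactly: 75 patients, 11 female / 64 male, 62 type-2 diabetics,
surgical-intervention groups of 24/4/5/18/7/10/6/1, 15 patients with 30 or
more outpatient visits, and per-group visit layouts that hit each group's
published minimum, median and maximum with a pooled median of 20. Because
per-patient values were never published, all other continuous fields
replicate the published medians (labs, lengths of stay) or published
per-group medians (outpatient visit costs); only the marginal counts are
claimed exact. One published group median (16.5 visits in a 5-patient
group) is unattainable with integer visit counts and is represented by 16.

**Stochastic mode** (`generate_cohort()`) draws every field:

* Clinical signs are independent Bernoulli draws at the published
  prevalences (purulent discharge 52%, erythema 68%, swelling 74%,
  gangrene 29%, limited joint motion 35%).
* Labs and lengths of stay are normal draws matched to the published
  mean/SD, truncated by rejection to the published min–max, with day
  counts rounded.
* Outpatient visits are `7 + NegBin(mu = 15.29, size = 2.21)`: the
  published counts are over-dispersed (mean 22.29, SD 11.01) with a hard
  floor at 7, and the negative binomial is moment-matched to the shifted
  mean and variance. Around 20% of draws land at 30+ visits, matching the
  published 15/75 tail.
* Cost components are lognormal, moment-matched to the published
  mean/SD and clipped to the published ranges. A lognormal is the natural
  choice because every published cost row has median < mean
  (right-skewed) and costs are nonnegative.
* Indirect cost is `incapacity_days × daily_wage` (human-capital
  approach). The wage default (9.82 USD/day) makes the 102-day maximum
  correspond to the published maximum incapacity cost; it is plainly a
  placeholder and should be set to the national average wage for real
  analyses.

All draws come from one seeded generator in a documented order, so cohorts
are bit-reproducible given the seed.

What the generator does **not** emulate: correlation structure
(visit-heavy patients do not get systematically higher outpatient costs;
signs are independent), microbiology, infection location, and any
time-course within the year. Tests that pass on synthetic cohorts
therefore validate the pipeline's computations, not clinical claims about
real data.

## Currency restatement

Historical local-currency amounts are restated in Q4-2022 US dollars in a
fixed order: divide by the year's annual-average exchange rate (local per
USD), then multiply by the CPI ratio `cpi[2022Q4] / cpi[year]`. Source
years use annual-average CPI; only the target uses a quarterly index,
since only the target period is specified to the quarter. The conversion
is linear and monotone, which the test suite asserts as properties.
Packaged FX/CPI tables are illustrative, for offline tests and demos; real
analyses should supply the official ECB and BLS series as CSVs
(`read_conversion_tables()`), which are validated strictly on load.

## Cost aggregation

Aggregation is bottom-up: items are converted, then summed by category per
patient. Two derived quantities are defined self-consistently:

* `total` is the exact sum of the package's own category totals. The
  calibrating publication's printed component means do not sum to its
  printed total (≈ 23.5k vs 24.6k USD; the residual components are not
  listed), so the package enforces additivity rather than reproducing the
  printed total.
* `subtotal_without_surgical` is defined as `total − surgical`; the source
  names such a row without a formula.

SD uses the sample (n−1) denominator; an n = 1 summary reports SD 0 with a
`degenerate_n` flag. Monetary rounding (half-even, 2 decimals) happens
only at presentation; internal arithmetic is unrounded.

## The Monte Carlo engine

Five inputs are drawn per iteration and composed linearly (see the
README). Design choices that were genuinely open:

* **Composition formula.** The calibrating description names the inputs
  but not how they combine; the linear composition with three unit-cost
  coefficients is the simplest model consistent with the named cost
  categories. The coefficients default to placeholders
  (`antibiotic_cost_per_day` 250 TRY, `reinfection_episode_cost` 9000
  TRY, `daily_wage` 500 TRY, all 2022) and are prominently configurable.
* **Re-infection** is two-stage: a Beta(3, 20) probability is drawn, then
  a Bernoulli event at that probability. This propagates the uncertainty
  of the rate itself instead of fixing it at the Beta mean.
* **Event rule.** Events fire when a uniform deviate is below `p`, which
  is exact. The spreadsheet-style rule of drawing an integer 00–99 and
  firing up to a two-digit threshold inclusive fires with probability
  `(round(100p)+1)/100` — 67% at a nominal 66% — and is kept only as a
  documented compatibility mode (`event_rule = "integer_percent"`).
* **Iterations** default to 10,000; 5,000 is equally defensible and a
  one-line configuration change.
* **CI method** is the 2.5th/97.5th percentile interval (no method is
  prescribed by the source); a normal-approximation interval is available.
* **PSA statistic** is the Spearman rank correlation of each input's
  draws with the totals; a tornado-style ranking is `abs()` of it. Rank
  correlation is the conventional choice when the composition is monotone
  but not linear in effect on ranks.
* **Currency of composition.** Inputs are TRY-denominated as quoted;
  conversion to USD happens after composition, through the same pipeline
  as the cohort costs.

Degenerate (point-mass) inputs are supported and give exactly the
hand-computable linear total, which anchors the engine's unit tests.
Normal and lognormal inputs may be truncated at zero by rejection;
rejection loops are capped (1000 rounds) and then clipped, so badly
mis-specified inputs still terminate.

## Group comparison

The Kruskal–Wallis H uses average ranks with the standard tie correction
`1 − Σ(t³−t)/(N³−N)`; when every pooled value is tied the statistic is 0
and p is 1 by convention. p-values come from χ²(k−1), or from the
permutation null: all distinct group assignments are enumerated when
their multinomial count is ≤ 10⁵ (always the case at pooled n ≤ 12),
otherwise random permutations with the add-one estimator
`(1 + #{H* ≥ H}) / (B + 1)`. Comparisons keep single-patient groups in
the statistic (their rank is well-defined) but suppress their SD in the
output, since a one-observation SD is undefined. The package deliberately
does not treat the published H and p values as reproduction targets:
they depend on the unpublished per-patient data.

## Problem sizes and tolerances in the test suite

Stochastic checks run at n = 10,000 draws against closed-form moments
with a 3-standard-error band; sign-prevalence recovery uses the exact
binomial SE. The type-I-error property uses 2,000 null datasets of four
groups of five with 199 permutations each, so the nominal rejection rate
at α = 0.05 is exact by the permutation-rank argument, and the empirical
rate is checked within 3 binomial SEs. The worked currency case (100 TRY
at 5 TRY/USD and a 1.2 CPI ratio → 24.00 USD) is asserted exactly to 2
decimals. The full suite runs in well under a minute on one CPU.

## Limitations

* Generated fields are mutually independent; real visit counts and
  outpatient costs are correlated, so cohort-level variance of totals is
  understated.
* The unit-cost coefficients of the simulation are placeholders; absolute
  simulated totals are meaningful only after local calibration.
* The packaged FX/CPI tables are demonstration series, not official
  statistics.
* The simulator draws per-scenario costs; it is not a patient-level
  microsimulation or Markov model and has no state transitions.
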