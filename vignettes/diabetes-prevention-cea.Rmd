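---
title: "Methods: a Markov cohort model for diabetes-prevention cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for diabetes-prevention cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dcea)
```

## The decision problem and the model

The package evaluates a group-based lifestyle programme (screening by
questionnaire, an eight-week course, then mentoring) offered to adults at
risk of type 2 diabetes, against no programme. Health is collapsed into
four states — normal glucose tolerance (NGT), impaired glucose tolerance
(IGT), diagnosed type 2 diabetes (T2D), and dead — and a cohort is pushed
through one-year cycles from its entry age to age 100. The model is
Markovian: transition probabilities depend only on the current state, the
current age band, and the years since programme start (through effect
decay); there are no tunnel states, no complication sub-states, and no
memory of how long a person has been diabetic.

Key structural assumptions, all deliberate simplifications:

* NGT→T2D and T2D→NGT are structural zeros: diabetes is entered and left
  only through IGT.
* Mortality differs by state only through the diabetes-attributable excess
  `t2d2d` added to the T2D state; IGT carries no excess mortality.
* Within a state, both arms share the same utility weight and the same
  annual health-care cost; the intervention acts purely through
  transitions.
* The intervention's full effect applies in programme year 1 and decays
  linearly to zero at the effect horizon (default 7 years, i.e. weight
  `(7 - t)/6`), after which both arms are identical. Programme costs stop
  after the participation horizon (default 5 years).

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `ngt2igt` | 0.163 / 0.152 | 1/yr | control / intervention |
| `igt2ngt` | 0.162 / 0.177 | 1/yr | control / intervention |
| `igt2t2d` | 0.060 / 0.030 | 1/yr | control / intervention |
| `t2d2igt` | 0.005 | 1/yr | equal in both arms (conservative) |
| `cNGT`, `cIGT`, `cT2D` | 1744.21, 2696.48, 5861.92 | EUR/yr | 2007 EUR; `cIGT = 0.46 · cT2D` |
| programme cost | 390.43 year 1; 189.93 years 2–5 | EUR/yr | itemised build-up in `intervention_cost_schedule()` |
| `uNGT`, `uIGT`, `uT2D` | m: 0.772, 0.764, 0.724; f: 0.747, 0.740, 0.701 | – | `uIGT = round(0.99 · uNGT, 3)`; dead = 0 |
| discount | 0.03 / 0.03 | 1/yr | costs / QALYs, separately configurable |
| initial occupancy | (0.84, 0.16, 0, 0) | – | NGT, IGT, T2D, dead |
| entry ages | 30, 50, 70 | yr | both sexes; horizon age 100 |

Stay probabilities are computed as row residuals so that every row sums to
one exactly; the published stay entries for the IGT row are internally
inconsistent with their own exit probabilities by a few thousandths and are
therefore not used.

Sampling distributions for the probabilistic analysis follow the standard
health-economics conventions: Beta for probabilities and utilities, fitted
by the method of moments from (mean, SE); Gamma for costs with SE set equal
to the mean, which gives the unit-shape (exponential) special case. The
published distribution table's Beta shape parameters disagree slightly with
a strict moment fit of its own (mean, SE) columns (the transition rows were
evidently normalised to an effective sample size of 100); the package
computes shapes from moments by default because that rule is reproducible,
and accepts explicit `alpha`/`beta` overrides in the configuration file for
anyone who wants the printed shapes verbatim.

## Mortality and the synthetic life table

The model needs, per sex and age band (<35, 35–64, 65–74, ≥75; boundaries
belong to the upper band), the non-diabetes death probability `mr` and the
T2D excess `t2d2d`. From a life table with columns
`age, sex, population, deaths_total, deaths_diabetes`, `mr` is
(deaths − diabetes deaths)/population aggregated over the band.

Two conventions are implemented for `t2d2d`:

* **attributable share** (default): `t2d2d = deaths_diabetes/population`,
  the diabetes-attributable share of the all-cause rate applied directly as
  the T2D excess. This matches how the source analysis describes its own
  construction (an attributable percentage applied to the `mr` figures).
* **prevalence division**: `t2d2d = fraction · rate / prevalence`, capped
  at `1 − mr`, which concentrates the attributable deaths in the diabetic
  sub-population and is the dimensionally strict reading. It needs
  band-level prevalence as an extra input and yields a several-fold larger
  excess at older ages.

Both are exposed (`mortality_from_life_table(method = ...)`); the default
was chosen because only the attributable-share convention reproduces the
small incremental QALY gains of the published base case.

The original analysis used a regional 2006 life table and
attributable-mortality fractions that are not published. The package
therefore generates a synthetic stand-in: Gompertz–Makeham hazards
`h(a) = A + B·exp(C·a)` per sex, converted to `q(a) = 1 − exp(−h(a))`, with
a survivorship-weighted population column and band-level attributable
fractions fixed a priori at an age-increasing profile of the kind reported
for low-mortality European populations (male 0.5/8/11/9%, female
0.5/10/14/12% across the four bands). The `"german-like-2006"` preset's six
hazard coefficients were then calibrated, by relative least squares, to the
twelve published no-intervention lifetime levels (discounted cost and QALYs
for ages 30/50/70 × both sexes). Two consequences should be kept in mind:

* the calibration targets are *levels* of the no-intervention arm only;
  the incremental results (ICERs) are genuine model outputs, not fitted
  quantities, and the acceptance suite treats them as validation;
* the preset reproduces band-level behaviour, not single-age rates — its
  young-adult `q(a)` is higher than any real German schedule because the
  band structure forces the <35 and 35–64 bands to carry the mortality the
  published QALY levels imply. It is a synthetic emulation for testing and
  reproduction, not a demographic estimate.

Passing tests on this preset therefore show that the pipeline reproduces
the published mechanism under a faithful stand-in environment; they do not
validate the model against real vital statistics.

## Numerical conventions

* Rewards accrue at cycle start; cycle *t* (0-based) is discounted by
  `(1+r)^-t`; no half-cycle correction. The final cycle at the horizon age
  contributes rewards but no further transition.
* The cohort ages one year per cycle and looks its mortality band up from
  its current age; ages beyond the table reuse the ≥75 band.
* Programme costs are paid by the alive fraction of the cohort.
* All arithmetic is at full double precision; rounding (2 decimals for
  EUR, 3 for utilities) happens only in `summary()`/export.
* ICERs with a zero QALY difference are `NA` (undefined), never `Inf`; every
  ratio carries its cost-effectiveness-plane quadrant because a bare
  negative ICER is ambiguous.
* CEAC ties (net benefit exactly zero) count as not cost-effective.
* PSA draws that would give the IGT row a negative residual are rejected
  and redrawn (bounded at 100 attempts). Degenerate distributions
  (`se = 0`) are point masses, which makes the fully degenerate PSA
  coincide with the deterministic pipeline — a property the test suite
  checks end to end.

## Probabilistic analysis: open choices and how they were resolved

* The intervention arm's transitions have no published distributions. By
  default each control draw is scaled by the deterministic
  intervention/control ratio (preserving the relative effect, e.g. halving
  `igt2t2d`), with an `independent` sampling switch available. The ratio
  default keeps the effect estimate out of the uncertainty being
  propagated, which is what the paired-arm CEAC interpretation needs.
* Costs and utilities are shared between arms within a draw (common random
  parameters); mortality is not sampled (no published distribution).
* Utility draws are sampled independently per state. The published moments
  place `uNGT` and `uIGT` so close (e.g. 0.772 vs 0.764 with SEs 0.004 and
  0.006) that enforcing the ordering `uT2D ≤ uIGT ≤ uNGT` by rejection
  would discard roughly one draw in eight and bias the means away from
  their specified values; the ordering is therefore enforced only for
  deterministic parameter sets.
* The single "cost of intervention" Gamma (mean 230.03, the annualised
  programme cost) scales the whole year-1/follow-up schedule
  proportionally in each draw.
* The number of draws is a free choice (the source analysis does not state
  its own); the default is 10,000, and the package records the seed in
  every PSA result so draw sets are bit-reproducible.

## Problem sizes in the test suite

The suite simulates lifetime cohorts (31–71 cycles), uses 2,000-draw PSAs
for Monte-Carlo-mean checks, 400-draw PSAs for CEAC shape properties,
10^5 draws for distribution-moment and Kolmogorov–Smirnov checks, and a
50,000-individual microsimulation as the independent oracle for the cohort
engine (agreement required within three Monte-Carlo standard errors).
These sizes keep the whole suite under a minute while leaving Monte-Carlo
error well below the tolerances being asserted.

## Known limitations

* No complication sub-states, production gains, screening utility, or
  hyperglycaemia-specific mortality beyond `t2d2d`; no currency conversion
  or inflation engine (all costs are 2007 EUR).
* Band-level mortality makes survival coarse at band edges (a 70-year-old
  carries the 65–74 band rate for five years, then jumps).
* The synthetic mortality preset is calibrated, not observed; analyses of
  real populations should supply their own life table CSV and, if
  available, measured `t2d2d` values via the direct override.
* The published incremental cost at age 70 is below what any `t2d2d`
  between zero and the prevalence-division value yields under the published
  transition and cost parameters, so the men-70 ICER lands above the
  published point estimate; the acceptance suite documents this gap rather
  than hiding it.
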