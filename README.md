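# t2dcea

Lifetime cost-effectiveness of lifestyle programmes that prevent type 2
diabetes, evaluated with a four-state Markov cohort model.

## Who this is for

Health economists and epidemiological modellers who want a tested,
configurable implementation of the classic decision-analytic question: *is a
screening + course + mentoring lifestyle programme for people at risk of
diabetes worth its cost over a lifetime horizon?* The package reproduces the
full pipeline — deterministic cohort model, probabilistic sensitivity
analysis (PSA), cost-effectiveness acceptability curves (CEAC), and one-way
sensitivity analyses — entirely from code, including a synthetic life-table
generator so no external data downloads are needed.

## The model

A cohort enters at age *a₀* distributed over four health states — normal
glucose tolerance (NGT), impaired glucose tolerance (IGT), diagnosed type 2
diabetes (T2D), and dead — with 84% NGT and 16% IGT. Each one-year cycle
the occupancy vector **x**ₜ advances through a row-stochastic matrix **P**ₜ,

  **x**ₜ₊₁ = **x**ₜ **P**ₜ,

where **P**ₜ combines (i) annual glycaemic transitions (NGT↔IGT, IGT→T2D,
T2D→IGT; NGT→T2D and T2D→NGT are structural zeros), (ii) band-level
mortality — NGT/IGT die with the non-diabetes probability *mr*[age, sex],
T2D with *mr* + *t2d2d*, the diabetes-attributable excess — and (iii) the
intervention effect, which is full in year 1 and decays linearly to zero at
the effect horizon *H* (default 7): the intervention arm uses
*p* = *p*ᶜᵗʳˡ + *w*(*p*ⁱⁿᵗ − *p*ᶜᵗʳˡ) with *w* = max(0, (*H*−*t*)/(*H*−1)).

Per cycle *t* (0-based) the cohort accrues discounted rewards
(1+*r*)⁻ᵗ [Σ xₛ·cₛ + programme cost] and (1+*r*)⁻ᵗ Σ xₛ·uₛ with *r* = 3%,
state costs *c* (EUR/year) and utilities *u* (dead: zero both). Programme
costs (EUR 390.43 in year 1, EUR 189.93 in years 2–5) are paid by the alive
fraction only. The incremental cost-effectiveness ratio is
ICER = ΔC/ΔQALY between the two arms, always reported with its
cost-effectiveness-plane quadrant. The PSA samples transition probabilities
and utilities from Beta distributions (method of moments on published
mean/SE pairs) and costs from unit-shape Gamma distributions, pairs both
arms on common draws, and summarises the draw cloud as a CEAC,
P(λ·ΔQ − ΔC > 0) over willingness-to-pay λ.

Because the regional life table behind *mr* and *t2d2d* is not published,
the package ships a synthetic Gompertz–Makeham generator
(`synthetic_life_table()`) whose `"german-like-2006"` preset is calibrated
to the published lifetime cost/QALY levels; see the methods vignette
(`vignettes/diabetes-prevention-cea.Rmd`) for exactly what that calibration
does and does not claim.

## Worked example

```r
library(t2dcea)
fit <- t2d_cea()        # base-case parameters, synthetic german-like mortality
summary(fit)
```

```
Discounted lifetime results per person (EUR, QALYs) and ICER (EUR/QALY)
 age    sex cost_control cost_intervention qalys_control qalys_intervention
  30   male     75453.05          74937.92         17.73              17.75
  50   male     51478.52          51238.96         13.45              13.48
  70   male     20019.36          20501.32          6.29               6.30
  30 female     82417.78          81821.00         18.38              18.40
  50 female     57889.58          57550.51         14.27              14.29
  70 female     24770.08          25166.89          7.26               7.28
   icer                   quadrant
 -22677 cost-saving-more-effective
 -11437 cost-saving-more-effective
  35598                  trade-off
 -26599 cost-saving-more-effective
 -15400 cost-saving-more-effective
  21855                  trade-off
```

Entering at 30 or 50, the intervention both gains QALYs and saves money
(negative ICER, cost-saving quadrant); at 70 it gains QALYs at a positive
price per QALY, lower for women than for men. The effect horizon is the
most influential assumption:

```r
one_way_sensitivity(fit$params, fit$mortality, "effect_horizon", c(3, 7, 20), ages = 70)
```

shows the age-70 ICER moving from ≈ EUR 154,525 (men) / 120,197 (women) per
QALY under a 3-year effect to negative (cost-saving) under a 20-year
effect. PSA and CEAC:

```r
psa <- simulate(fit, nsim = 2000, seed = 1, scenario = "male_50")
plot(psa_ceac(psa))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/t2dcea.R` (subcommands `run`, `sensitivity`, `psa`, `ceac`,
`synth`; every run writes a manifest of its outputs).

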