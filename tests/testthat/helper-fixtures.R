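# Shared fixtures, built in code at test time.

# Parameter bundle whose sampling distributions are point masses centred on
# the bundle's deterministic values, so that PSA draws reproduce the
# deterministic pipeline exactly. (The published distribution table centres
# igt2t2d at 0.062 while the deterministic transition table uses 0.06, so
# the point masses are rebuilt from the deterministic fields.)
degenerate_params <- function() {
  p <- default_parameters()
  tr <- p$transitions$control
  point <- function(family, mean) dist_spec(family, mean, 0)
  p$distributions <- list(
    ngt2igt = point("beta", tr$ngt2igt),
    igt2ngt = point("beta", tr$igt2ngt),
    igt2t2d = point("beta", tr$igt2t2d),
    t2d2igt = point("beta", tr$t2d2igt),
    cNGT = point("gamma", unname(p$costs["NGT"])),
    cIGT = point("gamma", unname(p$costs["IGT"])),
    cT2D = point("gamma", unname(p$costs["T2D"])),
    intervention_cost = point("gamma", p$intervention_cost$annualised),
    uNGT_male = point("beta", unname(p$utilities$male["NGT"])),
    uNGT_female = point("beta", unname(p$utilities$female["NGT"])),
    uIGT_male = point("beta", unname(p$utilities$male["IGT"])),
    uIGT_female = point("beta", unname(p$utilities$female["IGT"])),
    uT2D_male = point("beta", unname(p$utilities$male["T2D"])),
    uT2D_female = point("beta", unname(p$utilities$female["T2D"])))
  p
}

# Immortal-cohort parameters with an identity alive-state matrix: occupancy
# never moves, so rewards are exact annuities.
annuity_params <- function(u = 0.772, cost = 0, rate = 0.03) {
  p <- default_parameters()
  zeroes <- list(ngt2igt = 0, igt2ngt = 0, igt2t2d = 0, t2d2igt = 0)
  p$transitions$control <- zeroes
  p$transitions$intervention <- zeroes
  p$costs[] <- cost
  p$utilities$male[] <- u
  p$utilities$female[] <- u
  p$discount[] <- rate
  p
}

# Tiny two-band life table with easy numbers, both sexes, all four bands.
small_life_table <- function() {
  ages <- c(20, 40, 70, 80)
  rows <- list()
  for (sx in c("male", "female")) {
    mult <- if (sx == "male") 1 else 0.5
    rows[[sx]] <- data.frame(
      age = ages, sex = sx,
      population = rep(10000, 4),
      deaths_total = c(10, 40, 250, 900) * mult,
      deaths_diabetes = c(0, 4, 30, 90) * mult)
  }
  life_table(
    age = c(rows$male$age, rows$female$age),
    sex = c(rows$male$sex, rows$female$sex),
    population = c(rows$male$population, rows$female$population),
    deaths_total = c(rows$male$deaths_total, rows$female$deaths_total),
    deaths_diabetes = c(rows$male$deaths_diabetes, rows$female$deaths_diabetes))
}

expect_occupancy_conserved <- function(trace, tol = 1e-12) {
  sums <- rowSums(trace[, c("share_ngt", "share_igt", "share_t2d", "share_dead")])
  expect_true(all(abs(sums - 1) < tol))
}
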