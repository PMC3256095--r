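# ICER classification, acceptability curves, one-way sensitivity.

fake_sim <- function(arm, cost, qalys, sex = "male", age = 50) {
  structure(list(arm = arm,
                 scenario = t2d_scenario(sex, age),
                 discounted_cost = cost, discounted_qalys = qalys),
            class = "cohort_sim")
}

test_that("ICER quadrants follow the signs of the increments", {
  r <- icer(fake_sim("control", 1000, 10), fake_sim("intervention", 900, 10.1))
  expect_equal(r$icer, -1000)
  expect_equal(r$quadrant, "cost-saving-more-effective")

  r <- icer(fake_sim("control", 1000, 10), fake_sim("intervention", 1100, 10.01))
  expect_equal(r$icer, 10000)
  expect_equal(r$quadrant, "trade-off")

  r <- icer(fake_sim("control", 1000, 10), fake_sim("intervention", 1000, 10.1))
  expect_equal(r$icer, 0)
  expect_equal(r$quadrant, "trade-off")

  r <- icer(fake_sim("control", 1000, 10), fake_sim("intervention", 1100, 9.9))
  expect_equal(r$quadrant, "dominated")

  r <- icer(fake_sim("control", 1000, 10), fake_sim("intervention", 900, 9.9))
  expect_equal(r$quadrant, "less-costly-less-effective")

  # zero QALY difference: ratio undefined, not a number
  r <- icer(fake_sim("control", 1000, 10), fake_sim("intervention", 1100, 10))
  expect_true(is.na(r$icer))

  expect_error(icer(fake_sim("control", 1, 1),
                    fake_sim("intervention", 1, 1, sex = "female")),
               "different scenarios")
  expect_error(icer(fake_sim("intervention", 1, 1), fake_sim("control", 1, 1)),
               "control")
})

test_that("CEAC is the INB exceedance probability with ties not cost-effective", {
  # dominant draws: probability one everywhere
  cc <- ceac(rep(-10, 4), rep(0.1, 4), wtp = c(0, 1000, 50000))
  expect_equal(cc$probability, c(1, 1, 1))

  # single draw: step function around its ICER, tie counts as not CE
  cc <- ceac(100, 0.01, wtp = c(0, 5000, 10000, 15000))
  expect_equal(cc$probability, c(0, 0, 0, 1))

  # symmetric draws around zero INB at lambda*
  set.seed(11)
  dq <- rep(0.01, 2000)
  dc <- 100 + c(rnorm(1000, -20, 5), rnorm(1000, 20, 5))
  cc <- ceac(dc, dq, wtp = 10000)
  expect_equal(cc$probability, 0.5, tolerance = 0.05)

  expect_error(ceac(numeric(0), numeric(0)), "at least one draw")
  expect_error(ceac(1, 0.1, wtp = c(2, 1)), "increasing")
})

test_that("CEAC is non-decreasing in lambda when all draws gain QALYs", {
  set.seed(3)
  for (rep in 1:5) {
    dc <- rnorm(300, 0, 500)
    dq <- abs(rnorm(300, 0.02, 0.02))
    cc <- ceac(dc, dq)
    expect_true(all(diff(cc$probability) >= 0))
  }
})

test_that("probability at lambda = 0 is the cost-saving fraction", {
  set.seed(5)
  dc <- rnorm(500); dq <- rnorm(500, 0.01, 0.05)
  cc <- ceac(dc, dq, wtp = c(0, 1000))
  expect_equal(cc$probability[1], mean(dc < 0))
})

test_that("one-way sensitivity at the base case reproduces the base ICER exactly", {
  fx <- fixture_scenario("paper-base")
  base <- t2d_cea(fx$params, fx$mortality, ages = c(50, 70))
  tab <- one_way_sensitivity(fx$params, fx$mortality, axis = "discount_rate",
                             values = 0.03, ages = c(50, 70))
  merged <- merge(base$summary, tab, by = c("age", "sex"))
  expect_equal(merged$icer.x, merged$icer.y, tolerance = 1e-12)

  tabH <- one_way_sensitivity(fx$params, fx$mortality, axis = "effect_horizon",
                              values = 7, ages = c(50, 70))
  mergedH <- merge(base$summary, tabH, by = c("age", "sex"))
  expect_equal(mergedH$icer.x, mergedH$icer.y, tolerance = 1e-12)
})

test_that("deterministic ICER is invariant to cohort scale (per-person model)", {
  # occupancy is a distribution, so results are per person by construction;
  # doubling all cost parameters doubles the ICER instead
  fx <- fixture_scenario("paper-base")
  p2 <- fx$params
  p2$costs <- fx$params$costs * 2
  s2 <- p2$intervention_cost
  for (f in c("screening", "course", "course_total", "followup", "followup_total",
              "followup_year1", "year1_total", "annualised"))
    s2[[f]] <- s2[[f]] * 2
  p2$intervention_cost <- s2
  sc <- fx$scenarios$male_70
  r1 <- icer(simulate_cohort(sc, "control", fx$params, fx$mortality),
             simulate_cohort(sc, "intervention", fx$params, fx$mortality))
  r2 <- icer(simulate_cohort(sc, "control", p2, fx$mortality),
             simulate_cohort(sc, "intervention", p2, fx$mortality))
  expect_equal(r2$icer, 2 * r1$icer, tolerance = 1e-10)
})
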