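# Cohort engine: effect blending, mortality embedding, recursion, rewards.

test_that("effect blending is full in year 1, linear, and gone from the horizon", {
  p <- default_parameters()
  expect_equal(blend_transition(1, p, "intervention")["IGT", "T2D"], 0.03)
  expect_equal(blend_transition(4, p, "intervention")["IGT", "T2D"], 0.045)
  expect_equal(blend_transition(7, p, "intervention")["IGT", "T2D"], 0.06)
  expect_equal(blend_transition(30, p, "intervention")["IGT", "T2D"], 0.06)
  # control arm never blends
  expect_equal(blend_transition(1, p, "control")["IGT", "T2D"], 0.06)
  # rows re-sum to one at every weight
  for (y in 1:8)
    expect_equal(unname(rowSums(blend_transition(y, p, "intervention"))), rep(1, 3))
  p$effect$horizon <- 1
  expect_error(blend_transition(1, p, "intervention"), "horizon >= 2")
})

test_that("mortality embedding scales alive rows and routes to Dead", {
  p <- default_parameters()
  alive <- arm_matrix(p, "intervention")
  z <- zero_mortality()
  P0 <- embed_mortality(alive, z, 50, "male")
  expect_equal(P0[1:3, 1:3], unclass(alive), ignore_attr = TRUE)
  expect_equal(unname(P0[, 4]), c(0, 0, 0, 1))

  mr <- matrix(0.1, 2, 4); t2 <- matrix(0, 2, 4)
  m <- mortality_model(mr, t2)
  P <- embed_mortality(alive, m, 50, "male")
  expect_equal(unname(P["NGT", ]), c(0.848 * 0.9, 0.152 * 0.9, 0, 0.1))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-15)

  # T2D state with certain death
  m1 <- mortality_model(matrix(0.2, 2, 4), matrix(0.8, 2, 4))
  P1 <- embed_mortality(alive, m1, 50, "male")
  expect_equal(unname(P1["T2D", ]), c(0, 0, 0, 1))
})

test_that("programme costs accrue only during participation", {
  s <- intervention_cost_schedule()
  expect_equal(round(intervention_cost_stream(1, s), 2), 390.43)
  expect_equal(round(intervention_cost_stream(3, s), 2), 189.93)
  expect_equal(intervention_cost_stream(6, s), 0)
  eff <- list(participation_years = 2)
  expect_equal(intervention_cost_stream(3, s, eff), 0)
  expect_error(intervention_cost_stream(0, s), "1-based")
})

test_that("one control cycle reproduces the hand-computed occupancy", {
  p <- default_parameters()
  sc <- t2d_scenario("male", 50, max_age = 51)
  sim <- simulate_cohort(sc, "control", p, zero_mortality())
  expect_equal(sim$trace$share_ngt[2], 0.84 * 0.837 + 0.16 * 0.162)  # 0.729
  expect_equal(sim$trace$share_igt[2], 0.84 * 0.163 + 0.16 * 0.778)
  expect_equal(sim$trace$share_t2d[2], 0.16 * 0.06)
})

test_that("constant-reward immortal cohorts earn exact annuities", {
  # identity transitions, zero mortality: QALYs are a geometric series
  p0 <- annuity_params(u = 0.772, rate = 0)
  sc <- t2d_scenario("male", 50, max_age = 59)   # 10 reward cycles
  s <- simulate_cohort(sc, "control", p0, zero_mortality())
  expect_equal(s$discounted_qalys, 7.72)

  p3 <- annuity_params(u = 0.772, rate = 0.03)
  for (n in c(10, 41)) {
    sc <- t2d_scenario("male", 50, max_age = 50 + n - 1)
    s <- simulate_cohort(sc, "control", p3, zero_mortality())
    expect_equal(s$discounted_qalys, 0.772 * sum(1.03^(-(0:(n - 1)))),
                 tolerance = 1e-12)
    expect_equal(s$undiscounted_qalys, 0.772 * n, tolerance = 1e-12)
  }
})

test_that("occupancy is conserved and the dead share is monotone", {
  set.seed(7)
  fx <- fixture_scenario("paper-base")
  for (rep in 1:5) {
    # random valid parameter bundles
    p <- fx$params
    p$transitions$control <- as.list(setNames(
      c(runif(1), runif(1, 0, 0.5), runif(1, 0, 0.5), runif(1)),
      c("ngt2igt", "igt2ngt", "igt2t2d", "t2d2igt")))
    p$transitions$intervention <- p$transitions$control
    sc <- t2d_scenario(sample(c("male", "female"), 1), sample(c(30, 50, 70), 1))
    for (arm in c("control", "intervention")) {
      s <- simulate_cohort(sc, arm, p, fx$mortality)
      expect_occupancy_conserved(s$trace)
      expect_true(all(diff(s$trace$share_dead) >= -1e-15))
    }
  }
})

test_that("discounted totals never exceed undiscounted ones", {
  fx <- fixture_scenario("paper-base")
  s <- simulate_cohort(fx$scenarios$male_30, "intervention", fx$params, fx$mortality)
  expect_lt(s$discounted_cost, s$undiscounted_cost)
  expect_lt(s$discounted_qalys, s$undiscounted_qalys)
})

test_that("discounted QALYs strictly decrease as the discount rate rises", {
  fx <- fixture_scenario("paper-base")
  q <- sapply(c(0, 0.02, 0.05, 0.1), function(r) {
    p <- fx$params; p$discount[] <- r
    simulate_cohort(fx$scenarios$female_50, "control", p, fx$mortality,
                    keep_trace = FALSE)$discounted_qalys
  })
  expect_true(all(diff(q) < 0))
})

test_that("with equal utilities and no mortality the arms earn equal QALYs", {
  p <- default_parameters()
  p$utilities$male[] <- 0.75
  p$utilities$female[] <- 0.75
  sc <- t2d_scenario("male", 30)
  qc <- simulate_cohort(sc, "control", p, zero_mortality(), keep_trace = FALSE)
  qi <- simulate_cohort(sc, "intervention", p, zero_mortality(), keep_trace = FALSE)
  expect_equal(qc$discounted_qalys, qi$discounted_qalys, tolerance = 1e-12)
})

test_that("toy fixture matches the hand computation", {
  fx <- fixture_scenario("toy")
  s <- simulate_cohort(fx$scenarios$male_50, "control", fx$params, fx$mortality)
  expect_equal(s$discounted_qalys, 2.31866838, tolerance = 1e-9)
  expect_equal(s$discounted_cost, 3882.9882, tolerance = 1e-9)
})
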