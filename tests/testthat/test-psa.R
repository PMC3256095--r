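# Monte-Carlo parameter sampling and the paired-arm PSA.

test_that("sampled transition rows always sum to one", {
  set.seed(21)
  p <- default_parameters()
  for (i in 1:50) {
    s <- sample_parameters(p)
    for (arm in c("control", "intervention")) {
      m <- arm_matrix(s$params, arm)
      expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-15)
      expect_true(all(m >= 0))
    }
  }
})

test_that("intervention draws preserve the deterministic relative effect", {
  set.seed(22)
  p <- default_parameters()
  s <- sample_parameters(p)
  ctrl <- s$params$transitions$control
  intv <- s$params$transitions$intervention
  expect_equal(intv$igt2t2d / ctrl$igt2t2d, 0.03 / 0.06, tolerance = 1e-12)
  expect_equal(intv$ngt2igt / ctrl$ngt2igt, 0.152 / 0.163, tolerance = 1e-12)
  expect_equal(intv$igt2ngt / ctrl$igt2ngt, 0.177 / 0.162, tolerance = 1e-12)
})

test_that("degenerate distributions reproduce the deterministic bundle", {
  set.seed(23)
  p <- degenerate_params()
  s <- sample_parameters(p)
  expect_equal(s$params$transitions, p$transitions, tolerance = 1e-12)
  expect_equal(s$params$costs, p$costs, tolerance = 1e-12)
  expect_equal(s$params$utilities, p$utilities, tolerance = 1e-12)
  expect_equal(s$params$intervention_cost$year1_total,
               p$intervention_cost$year1_total, tolerance = 1e-12)
})

test_that("a fixed seed reproduces the draw records exactly", {
  fx <- fixture_scenario("paper-base")
  a <- run_psa(fx$scenarios$male_70, fx$params, fx$mortality, n_draws = 5, seed = 99)
  b <- run_psa(fx$scenarios$male_70, fx$params, fx$mortality, n_draws = 5, seed = 99)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(fx$scenarios$male_70, fx$params, fx$mortality, n_draws = 5, seed = 100)
  expect_false(identical(a$draws, c2$draws))
})

test_that("sampled parameters converge to their specified moments", {
  set.seed(24)
  p <- default_parameters()
  n <- 1e5
  x <- draw_dist(p$distributions$igt2t2d, n)
  expect_equal(mean(x), 0.062, tolerance = 3 * 0.024 / sqrt(n) / 0.062)
  expect_equal(sd(x), 0.024, tolerance = 0.02)
  # correct-family KS check, not rejected at alpha = 0.01
  f <- beta_from_moments(0.062, 0.024)
  ks <- suppressWarnings(ks.test(x, "pbeta", f$alpha, f$beta))
  expect_gt(ks$p.value, 0.01)
  # cost draws: unit-shape Gamma
  y <- draw_dist(p$distributions$cNGT, n)
  expect_equal(mean(y), 1744.21, tolerance = 0.02 * 1744.21)
  expect_equal(sd(y), 1744.21, tolerance = 0.05 * 1744.21)
})

test_that("PSA with one degenerate draw equals the deterministic pipeline", {
  fx <- fixture_scenario("paper-base")
  p <- degenerate_params()
  sc <- fx$scenarios$female_50
  psa <- run_psa(sc, p, fx$mortality, n_draws = 1, seed = 1)
  det <- icer(simulate_cohort(sc, "control", p, fx$mortality),
              simulate_cohort(sc, "intervention", p, fx$mortality))
  expect_equal(psa$draws$delta_cost, det$delta_cost, tolerance = 1e-9)
  expect_equal(psa$draws$delta_qalys, det$delta_qalys, tolerance = 1e-9)
})

test_that("mean PSA increments track the deterministic increments", {
  fx <- fixture_scenario("paper-base")
  sc <- fx$scenarios$male_70
  det <- icer(simulate_cohort(sc, "control", fx$params, fx$mortality),
              simulate_cohort(sc, "intervention", fx$params, fx$mortality))
  psa <- run_psa(sc, fx$params, fx$mortality, n_draws = 2000, seed = 4)
  se_q <- sd(psa$draws$delta_qalys) / sqrt(psa$n_draws)
  # near-linearity: Monte-Carlo mean close to the deterministic value
  expect_lt(abs(mean(psa$draws$delta_qalys) - det$delta_qalys), 5 * se_q)
  se_c <- sd(psa$draws$delta_cost) / sqrt(psa$n_draws)
  expect_lt(abs(mean(psa$draws$delta_cost) - det$delta_cost), 5 * se_c)
  # CEAC from the PSA behaves like a probability curve
  cc <- psa_ceac(psa)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
})

test_that("independent intervention sampling is available via config switch", {
  set.seed(26)
  p <- default_parameters()
  p$psa$intervention_sampling <- "independent"
  s <- sample_parameters(p)
  expect_true(all(unlist(s$params$transitions$intervention) >= 0))
  expect_true(all(unlist(s$params$transitions$intervention) <= 1))
})
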