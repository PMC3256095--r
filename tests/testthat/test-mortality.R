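# Life-table aggregation, age bands, and the diabetes-attributable excess.

test_that("age bands follow the model's stratification with upper-band boundaries", {
  expect_equal(band_for_age(34), "<35")
  expect_equal(band_for_age(35), "35-64")
  expect_equal(band_for_age(64), "35-64")
  expect_equal(band_for_age(65), "65-74")
  expect_equal(band_for_age(75), ">=75")
  expect_equal(band_for_age(80), ">=75")
  expect_error(band_for_age(-1), "\\[0, 120\\]")
})

test_that("mr subtracts diabetes deaths before dividing by population", {
  lt <- life_table(age = 50, sex = "male", population = 1000,
                   deaths_total = 10, deaths_diabetes = 2)
  mr <- mr_from_life_table(lt)
  expect_equal(mr["male", "35-64"], 0.008)
  # no diabetes deaths: mr equals the crude rate
  lt0 <- small_life_table()
  lt0$deaths_diabetes <- 0
  mr0 <- mr_from_life_table(lt0)
  expect_equal(mr0["male", ], c("<35" = 0.001, "35-64" = 0.004,
                                "65-74" = 0.025, ">=75" = 0.09))
})

test_that("band aggregation is consistent across resolutions and scale-invariant", {
  sp <- synthetic_mortality_params()
  lt <- synthetic_life_table(sp)
  mr_single <- mr_from_life_table(lt)

  # pre-aggregate ages into one row per band; weighted means must agree
  b <- band_for_age(lt$age)
  agg <- aggregate(cbind(population, deaths_total, deaths_diabetes) ~ sex + b,
                   data = cbind(lt, b = b), FUN = sum)
  agg$age <- c("<35" = 20, "35-64" = 50, "65-74" = 70, ">=75" = 80)[agg$b]
  lt_band <- life_table(agg$age, agg$sex, agg$population,
                        agg$deaths_total, agg$deaths_diabetes)
  expect_equal(mr_from_life_table(lt_band), mr_single, tolerance = 1e-12)

  # uniform scaling of population and deaths leaves mr unchanged
  lt2 <- lt
  lt2$population <- lt$population * 7
  lt2$deaths_total <- lt$deaths_total * 7
  lt2$deaths_diabetes <- lt$deaths_diabetes * 7
  expect_equal(mr_from_life_table(validate_life_table(lt2)), mr_single,
               tolerance = 1e-12)
})

test_that("t2d2d allocates the attributable share to the diabetic sub-population", {
  expect_equal(t2d2d_from_fraction(0, 0.5, 0.2), 0)
  expect_equal(t2d2d_from_fraction(0.1, 0.02, 0.1), 0.02)
  # capped at 1 - mr
  expect_equal(t2d2d_from_fraction(0.9, 0.5, 0.01, mr = 0.3), 0.7)
  expect_error(t2d2d_from_fraction(0.1, 0.02, 0), "positive")
  expect_error(t2d2d_from_fraction(1, 0.02, 0.1), "\\[0, 1\\)")
})

test_that("mortality model construction and lookups", {
  lt <- small_life_table()
  m <- mortality_from_life_table(lt, method = "attributable_share")
  # male >=75: rate 0.09, diabetes share 0.009
  expect_equal(unname(m$mr["male", ">=75"]), 0.081)
  expect_equal(unname(m$t2d2d["male", ">=75"]), 0.009)
  d <- state_death_probs(m, 80, "male")
  expect_equal(unname(d), c(0.081, 0.081, 0.09))
  # ages beyond the table reuse the >=75 band
  expect_equal(state_death_probs(m, 115, "male"), d)

  # prevalence convention inflates the excess by 1/prevalence
  prev <- matrix(0.1, 2, 4)
  mp <- mortality_from_life_table(lt, method = "prevalence", prevalence = prev)
  expect_equal(unname(mp$t2d2d["male", ">=75"]), 0.09)
  expect_error(mortality_from_life_table(lt, method = "prevalence"), "required")

  # incomplete tables cannot build a model
  expect_error(mortality_from_life_table(lt[lt$sex == "male", ]), "band")
})

test_that("life-table validation enforces its invariants", {
  expect_error(life_table(50, "male", 0, 0, 0), "positive")
  expect_error(life_table(50, "male", 100, 150, 0), "population")
  expect_error(life_table(50, "male", 100, 10, 20), "deaths_total")
  expect_error(life_table(50, "other", 100, 10, 2), "male")
})

test_that("life tables survive a CSV round trip", {
  lt <- small_life_table()
  f <- tempfile(fileext = ".csv")
  write_life_table(lt, f)
  lt2 <- read_life_table(f)
  expect_equal(as.data.frame(lt2), as.data.frame(lt), tolerance = 1e-12)
  expect_error(read_life_table(tempfile()), "not found")
})
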