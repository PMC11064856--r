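test_that("the length-AFDM allometry evaluates and increases correctly", {
  expect_equal(afdm_from_length(63.4), 0.0732989, tolerance = 1e-6)
  expect_equal(afdm_from_length(100), 0.3136407, tolerance = 1e-6)
  lens <- seq(20, 160, by = 5)
  expect_true(all(diff(afdm_from_length(lens)) > 0))
  expect_error(afdm_from_length(0), "positive")
})

test_that("fresh mass scales AFDM by the fixed ratio", {
  expect_equal(fresh_from_afdm(0), 0)
  expect_equal(fresh_from_afdm(1), 5.7904)
  expect_equal(fresh_from_afdm(0.0732989), 0.4244301, tolerance = 1e-6)
  expect_error(fresh_from_afdm(-1), "non-negative")
})

test_that("daily energy expenditure follows the mass power law", {
  expect_equal(dee(1), 1092)
  expect_equal(dee(0.109), 217.0234, tolerance = 1e-4)
  expect_equal(dee(0.0715), 159.5922, tolerance = 1e-4)
  m <- c(0.05, 0.1, 0.2)
  expect_equal(dee(2 * m) / dee(m), rep(2^0.729, 3))
  expect_error(dee(0), "positive")
})

test_that("pair DEE reproduces the printed integer and scales with mass", {
  expect_equal(pair_dee(), 377)
  raw <- pair_dee(rounded = FALSE)
  expect_gte(raw, 376)
  expect_lte(raw, 377.5)

  p_eq <- energetics_params(male_mass_kg = 0.09, female_mass_kg = 0.09)
  expect_equal(pair_dee(p_eq, rounded = FALSE), 2 * dee(0.09))
  p_half <- energetics_params(male_mass_kg = 0.109 / 2,
                              female_mass_kg = 0.0715 / 2)
  expect_equal(pair_dee(p_half, rounded = FALSE) / pair_dee(rounded = FALSE),
               0.5^0.729)
})

test_that("parent consumption is linear in the diet proportion", {
  expect_equal(parent_consumption(0), 0)
  expect_equal(parent_consumption(0.3), 1989.354, tolerance = 1e-6)
  expect_equal(parent_consumption(0.7), 4641.825, tolerance = 1e-6)
  p <- seq(0, 1, by = 0.1)
  expect_equal(parent_consumption(p), p * parent_consumption(1))
  expect_error(parent_consumption(1.3), "\\[0, 1\\]")
  expect_error(parent_consumption(-0.1), "\\[0, 1\\]")

  # family difference identity up to no rounding at all
  expect_equal(family_consumption(0.6) - family_consumption(0.25),
               parent_consumption(0.35))
})

test_that("worm-biomass conversions are mutually consistent", {
  params <- energetics_params()
  tab <- consumption_table(params)
  fam <- tab[tab$scope == "family", ]
  expect_equal(fam$fresh_g / fam$afdm_g,
               rep(params$fresh_to_afdm_ratio, nrow(fam)))
  # worms -> kJ -> worms closes the loop
  worms <- fam$afdm_g / params$mean_worm_afdm_g
  kj <- worms * params$mean_worm_afdm_g * params$worm_energy_density
  expect_equal(kj / (params$mean_worm_afdm_g * params$worm_energy_density),
               worms)
})

test_that("daily provisioning rates divide counts and biomass by hours", {
  vd <- rate_fixture(10, hours = 2)
  r <- daily_rates(vd)
  expect_equal(r$worms_per_hour, 5)

  # summed AFDM of 50 + 80 mm worms over one hour
  rows <- rbind(flat_row(units = 2.5, hours = 1),
                flat_row(units = 4, hours = 1))
  r2 <- daily_rates(as_visit_data(rows))
  expect_equal(r2$afdm_g_per_hour,
               afdm_from_length(50) + afdm_from_length(80))

  # a visit-less day with recorded hours is a valid zero-rate day
  extra <- data.frame(nest_id = "nest1", date = "2012-06-09",
                      recorded_hours_day = 2)
  r3 <- daily_rates(vd, extra_days = extra)
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$worms_per_hour[r3$date == "2012-06-09"], 0)

  # unmeasured worms count for rates but not biomass
  vd4 <- fixture_vd()
  r4 <- daily_rates(vd4)
  expect_equal(sum(r4$n_unmeasured_worms), 1L)
})

test_that("brood consumption chains rates through hours and duration", {
  # constant 5 worms/h: 5 x 15 x 12.05 = 903.75 per brood of five
  vd <- rate_fixture(c(5, 5))
  b <- brood_consumption(vd, nests = "all")
  expect_equal(b$per_nest$brood_worms, 903.75)
  expect_equal(b$per_nest$per_nestling_worms, 180.75)
  expect_equal(b$standardized_brood_worms, 903.75)

  # two days at 4 and 6 worms/h average to the same totals
  vd2 <- rate_fixture(c(4, 6))
  expect_equal(brood_consumption(vd2, nests = "all")$standardized_brood_worms,
               903.75)

  # the subset rule drops the nest with the fewest recorded days
  both <- rbind(rate_fixture(c(5, 5))$items[visit_cols_for_tests()],
                rate_fixture(8, nest_id = "nest2")$items[visit_cols_for_tests()])
  b3 <- brood_consumption(as_visit_data(both), nests = "subset")
  expect_equal(b3$nests_used, "nest1")
  b4 <- brood_consumption(as_visit_data(both), nests = "all")
  expect_equal(sort(b4$nests_used), c("nest1", "nest2"))
  expect_equal(b4$standardized_brood_worms,
               mean(c(180.75, 8 * 15 * 12.05 / 5)) * 5)
})
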