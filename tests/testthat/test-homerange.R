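test_that("predicted area scales as consumption over density x availability", {
  expect_equal(predicted_area(1, 1, 1), 1)
  expect_equal(predicted_area(5497, 8.7, 0.05), 12636.78, tolerance = 1e-6)
  expect_equal(predicted_area(855, 0.53, 0.005), 322641.5, tolerance = 1e-6)

  a <- seq(0.005, 0.05, length.out = 7)
  expect_true(all(diff(predicted_area(100, 1, a)) < 0))
  expect_true(all(diff(predicted_area(100, c(1, 2, 4), 0.01)) < 0))
  expect_true(all(diff(predicted_area(c(10, 20, 40), 1, 0.01)) > 0))
  expect_error(predicted_area(0, 1, 0.5), "positive")
  expect_error(predicted_area(1, 1, 0), "availability")
})

test_that("the predicted band is a proper interval, linear in consumption", {
  a <- c(0.005, 0.02, 0.05)
  b <- predicted_band(5497, a)
  expect_true(all(b[, "lower"] < b[, "upper"]))
  expect_equal(unname(b[1, "lower"]), 5497 / (8.7 * 0.005),
               tolerance = 1e-12)
  expect_equal(predicted_band(2 * 5497, a), 2 * b)
  expect_error(predicted_band(1, a, density_low = 2, density_high = 1),
               "density_low < density_high")
})

test_that("the overlap integral matches closed-form band geometry", {
  # disjoint bands give zero
  expect_equal(overlap_integral(1e9, observed_band = c(1e5, 3e5)), 0)
  # a band covering the observed interval everywhere gives width x domain
  full <- overlap_integral(100, observed_band = c(1e5, 3e5),
                           density_low = 1e-3, density_high = 1e6)
  expect_equal(full, 2e5 * 0.045, tolerance = 1e-10)

  # analytic piecewise oracle across constructed geometries
  cases <- list(
    list(N = 5496.785, band = c(1e5, 2e5)),
    list(N = 855, band = c(1e5, 2e5)),
    list(N = 2844.354, band = c(1e5, 3e5)),
    list(N = 4833.7, band = c(5e4, 2e5)),
    list(N = 300, band = c(2e4, 6e4)))
  for (cs in cases) {
    got <- overlap_integral(cs$N, observed_band = cs$band)
    want <- overlap_analytic_oracle(cs$N, cs$band)
    if (want == 0) expect_equal(got, 0) else
      expect_lt(abs(got - want) / want, 1e-3)
  }
  expect_equal(overlap_integral(5496.785, observed_band = c(1e5, 2e5)),
               4484, tolerance = 1e-3)
})

test_that("halving the integration step changes the integral by < 0.1%", {
  for (N in c(855, 5496.785)) {
    coarse <- overlap_integral(N, observed_band = c(1e5, 2e5), step = 1e-5)
    fine <- overlap_integral(N, observed_band = c(1e5, 2e5), step = 5e-6)
    expect_lt(abs(fine - coarse) / fine, 0.001)
  }
})

test_that("relative overlap indices are normalised to the set maximum", {
  expect_equal(relative_overlap_index(3.7), 100)
  idx <- relative_overlap_index(c(a = 1, b = 4, c = 0))
  expect_equal(unname(idx), c(25, 100, 0))
  expect_equal(relative_overlap_index(10 * c(1, 4, 0)), idx,
               ignore_attr = TRUE)
  expect_warning(z <- relative_overlap_index(c(0, 0)), "all overlaps")
  expect_equal(z, c(0, 0))
  expect_error(relative_overlap_index(-1), "non-negative")
})

test_that("the scenario grid orders overlaps as the diet proportion grows", {
  g <- scenario_grid()
  expect_true(all(g$index >= 0 & g$index <= 100))
  for (bn in unique(g$band)) {
    gb <- g[g$band == bn, ]
    fam <- gb[gb$scenario != "brood", ]
    expect_gte(fam$index[fam$p == 0.7], fam$index[fam$p == 0.3])
    expect_true(all(gb$overlap[gb$scenario == "brood"] < fam$overlap))
    expect_equal(max(gb$index), 100)
  }
  # the 10-20 ha narrow-band indices near the published comparison
  gb <- g[g$band == "10-20 ha", ]
  expect_equal(gb$index[gb$scenario == "family p=0.6"], 99.4,
               tolerance = 1e-3)
})
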