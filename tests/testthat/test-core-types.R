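test_that("visit classification partitions food-loads by earthworm content", {
  expect_identical(classify_visit(rep(TRUE, 3)), "OnlyE")
  expect_identical(classify_visit(FALSE), "NoE")
  expect_identical(classify_visit(c(TRUE, TRUE, FALSE)), "MIX")
  expect_error(classify_visit(logical(0)), "malformed visit")
  expect_error(classify_visit(c(TRUE, NA)), "malformed visit")

  # total over non-empty item sets, image exactly {NoE, OnlyE, MIX}
  set.seed(11)
  types <- replicate(200, {
    classify_visit(sample(c(TRUE, FALSE), sample(1:7, 1), replace = TRUE))
  })
  expect_true(all(types %in% c("NoE", "OnlyE", "MIX")))
})

test_that("time of day uses half-open categories over the 8-18 h window", {
  expect_equal(as.character(categorize_time("09:30")), "morning")
  expect_equal(as.character(categorize_time("10:00")), "noon")
  expect_equal(as.character(categorize_time("17:59")), "afternoon")
  expect_equal(as.character(categorize_time(c("08:00", "13:59", "14:00", "18:00"))),
               c("morning", "noon", "afternoon", "afternoon"))
  expect_error(categorize_time("07:59"), "out of observation window")
  expect_error(categorize_time("18:01"), "out of observation window")
  expect_error(categorize_time("930"), "unparseable")
})

test_that("rainfall of exactly 4 mm is light; heavy requires exceeding 4 mm", {
  expect_equal(as.character(categorize_rain(c(0, 4, 12.5))),
               c("light", "light", "heavy"))
  expect_equal(as.character(categorize_rain(4 + 1e-9)), "heavy")
  expect_error(categorize_rain(-0.1), "non-negative")
})

test_that("nestling age classes split at 7/8 days over the 1-13 range", {
  expect_equal(as.character(categorize_age(c(1, 7, 8, 13))),
               c("young", "young", "old", "old"))
  expect_error(categorize_age(0), "between 1 and 13")
  expect_error(categorize_age(14), "between 1 and 13")
  expect_error(categorize_age(6.5), "integer")
})

test_that("beak-unit lengths convert at 2 cm per unit and stay quantised", {
  expect_equal(beak_units_to_cm(3.25), 6.5)
  expect_equal(beak_units_to_cm(0.25), 0.5)
  expect_equal(beak_units_to_cm(7.75), 15.5)
  expect_error(beak_units_to_cm(0.3), "quantised")
  expect_error(beak_units_to_cm(0), "positive")
})

test_that("excluding first visits removes exactly one visit per session", {
  vd <- fixture_vd()
  kept <- exclude_first_visits(vd$visits)
  n_sessions <- length(unique(vd$visits$session_id))
  expect_equal(nrow(vd$visits) - nrow(kept), n_sessions)
  expect_true(all(!is.na(kept$inter_visit_interval_min)))

  # a single-visit session contributes nothing
  single <- vd$visits[vd$visits$session_id == "nest2/2013-06-05", ]
  expect_equal(nrow(exclude_first_visits(single)), 0L)
  expect_equal(nrow(exclude_first_visits(vd$visits[0, ])), 0L)
})
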