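test_that("composition percentages use identified items only", {
  items <- data.frame(taxon = rep(c("earthworm", "centipede", "unknown"),
                                  c(169, 30, 12)))
  comp <- composition(items)
  expect_equal(comp$percent[comp$taxon == "earthworm"],
               round(100 * 169 / 199, 1))
  expect_equal(attr(comp, "n_identified"), 199L)
  expect_equal(attr(comp, "n_unknown"), 12L)

  # invariant to row order and to presence of unknown rows
  shuffled <- items[sample(nrow(items)), , drop = FALSE]
  expect_equal(composition(shuffled), composition(items))
  no_unknown <- items[items$taxon != "unknown", , drop = FALSE]
  expect_equal(composition(no_unknown)$percent, comp$percent)

  expect_equal(composition(data.frame(taxon = rep("moth", 7)))$percent, 100)
  expect_error(composition(data.frame(taxon = character(0))), "no prey items")
})

test_that("visit-type proportions include the derived YesE share", {
  vt <- visit_type_proportions(
    data.frame(visit_type = rep(c("NoE", "OnlyE", "MIX"), c(1, 6, 3))))
  expect_equal(vt$count, c(1L, 6L, 3L, 9L))
  expect_equal(vt$percent, c(10, 60, 30, 90))
  all_only <- visit_type_proportions(data.frame(visit_type = rep("OnlyE", 5)))
  expect_equal(all_only$percent[all_only$visit_type == "OnlyE"], 100)
})

test_that("length summaries use sample SD and report exclusions", {
  rows <- rbind(flat_row(units = 2), flat_row(units = 3),
                flat_row(units = 4))  # 4, 6, 8 cm worms in one load
  ls <- length_summary(as_visit_data(rows))
  worm <- ls[ls$group == "earthworm", ]
  expect_equal(worm$mean_cm, 6)
  expect_equal(worm$sd_cm, 2)
  expect_equal(c(worm$min_cm, worm$max_cm), c(4, 8))
  expect_equal(attr(ls, "n_unmeasured"), 0L)

  single <- fixture_vd()
  ls2 <- length_summary(single)
  expect_equal(attr(ls2, "n_unmeasured"), 1L)
  expect_true(is.na(length_summary(rate_fixture(1))$sd_cm[1]))
})

test_that("the exact 2x2 test matches enumeration-derived probabilities", {
  expect_equal(fisher_exact_2x2(matrix(2, 2, 2)), 1)
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5))), 2 / 252)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact_2x2(rbind(c(1, -1), c(0, 2))), "non-negative")

  # agreement with the reference implementation across random tables
  set.seed(21)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher's combined probability behaves as a chi-square tail", {
  res <- fisher_combined(c(1, 1))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 4L)
  expect_equal(res$p_value, 1)

  res <- fisher_combined(c(0.05, 0.05))
  expect_equal(res$statistic, -4 * log(0.05), tolerance = 1e-12)
  # closed form of the 4-df upper tail: exp(-x/2) (1 + x/2)
  x <- res$statistic
  expect_equal(res$p_value, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(res$p_value, 0.017479, tolerance = 1e-4)

  # a single p-value round-trips through the 2-df tail
  for (p in c(0.01, 0.2, 0.9)) {
    expect_equal(fisher_combined(p)$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_combined(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combined(1.2), "\\(0, 1\\]")
})

test_that("age contingency combines per-nest exact tests", {
  vd <- fixture_vd()
  res <- age_contingency(vd, mode = "items")
  expect_s3_class(res, "contingency_result")
  expect_equal(res$combined$df, 2L * length(res$tables))
  expect_true(all(res$per_nest_p > 0 & res$per_nest_p <= 1))
  # unknown-taxon items stay out of the item-level tables
  expect_equal(sum(vapply(res$tables, sum, 0)),
               sum(vd$items$taxon != "unknown"))

  # a single nest reduces the combined p to that nest's exact p
  one <- as_visit_data(fixture_items()[1:9, ])
  res1 <- age_contingency(one, mode = "items")
  expect_equal(res1$combined$p_value, unname(res1$per_nest_p[1]))

  # a nest missing an age class is dropped with a warning, df adjusted
  rows <- fixture_items()
  young_only_n2 <- rows[!(rows$nest_id == "nest2" & rows$nestling_age_days > 7), ]
  expect_warning(res2 <- age_contingency(as_visit_data(young_only_n2),
                                         mode = "visits"),
                 "lacks one age class")
  expect_equal(res2$combined$df, 2L)
})

test_that("identical young/old composition gives a non-small combined p", {
  # balanced null case: same earthworm share in both age classes
  rows <- list()
  for (nest in c("nest1", "nest2")) {
    for (age in c(4L, 9L)) {
      date <- as.character(as.Date("2012-06-01") + age)
      for (v in 1:6) {
        rows[[length(rows) + 1L]] <- flat_row(
          nest_id = nest, date = date, session_order = (age > 7) + 1L,
          visit_order = v, clock_time = "11:00",
          interval = if (v == 1) NA_real_ else 20,
          taxon = if (v <= 4) "earthworm" else "beetle",
          units = 2, age = age)
      }
    }
  }
  vd <- as_visit_data(do.call(rbind, rows))
  res <- age_contingency(vd, mode = "items")
  expect_true(res$combined$p_value > 0.5)
})
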