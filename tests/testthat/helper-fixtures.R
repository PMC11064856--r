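# Fixtures built in code plus independent oracles used across test files.

flat_row <- function(nest_id = "nest1", date = "2012-06-04",
                     session_order = 1L, visit_order = 1L,
                     clock_time = "09:00", interval = NA_real_,
                     taxon = "earthworm", units = 3, pieces = 1L,
                     age = 4L, brood = 5L, rain = 0, hours = 4) {
  data.frame(nest_id = nest_id, date = date, session_order = session_order,
             visit_order = visit_order, clock_time = clock_time,
             inter_visit_interval_min = interval, taxon = taxon,
             is_earthworm = as.integer(taxon == "earthworm"),
             length_beak_units = units, n_sundered_pieces = pieces,
             nestling_age_days = age, brood_size = brood,
             rainfall_mm = rain, recorded_hours_day = hours,
             stringsAsFactors = FALSE)
}

# Two nests, four sessions, eight visits, thirteen prey items; covers both
# age classes per nest, an unmeasured worm, an unknown-taxon item, heavy
# and light rain, and all three visit types.
fixture_items <- function() {
  n1d1 <- list(
    flat_row(visit_order = 1L, clock_time = "09:00", units = 2),
    flat_row(visit_order = 1L, clock_time = "09:00", units = 3),
    flat_row(visit_order = 2L, clock_time = "09:30", interval = 30,
             units = 4, pieces = 2L),
    flat_row(visit_order = 2L, clock_time = "09:30", interval = 30,
             taxon = "beetle", units = 1.5),
    flat_row(visit_order = 3L, clock_time = "10:15", interval = 45,
             taxon = "centipede", units = 2))
  n1d2 <- list(
    flat_row(date = "2012-06-08", session_order = 2L, visit_order = 1L,
             clock_time = "14:00", units = 3.25, age = 8L, rain = 10,
             hours = 3),
    flat_row(date = "2012-06-08", session_order = 2L, visit_order = 2L,
             clock_time = "15:00", interval = 60, units = 1, age = 8L,
             rain = 10, hours = 3),
    flat_row(date = "2012-06-08", session_order = 2L, visit_order = 2L,
             clock_time = "15:00", interval = 60, units = NA_real_,
             age = 8L, rain = 10, hours = 3),
    flat_row(date = "2012-06-08", session_order = 2L, visit_order = 2L,
             clock_time = "15:00", interval = 60, taxon = "unknown",
             units = 1, age = 8L, rain = 10, hours = 3))
  n2d1 <- list(
    flat_row(nest_id = "nest2", date = "2013-06-05", visit_order = 1L,
             clock_time = "08:30", units = 2, age = 5L, brood = 6L,
             rain = 2, hours = 2),
    flat_row(nest_id = "nest2", date = "2013-06-05", visit_order = 1L,
             clock_time = "08:30", units = 2, age = 5L, brood = 6L,
             rain = 2, hours = 2))
  n2d2 <- list(
    flat_row(nest_id = "nest2", date = "2013-06-12", session_order = 2L,
             visit_order = 1L, clock_time = "16:00", taxon = "caterpillar",
             units = 1, age = 12L, brood = 6L, rain = 8, hours = 2.5),
    flat_row(nest_id = "nest2", date = "2013-06-12", session_order = 2L,
             visit_order = 2L, clock_time = "17:30", interval = 90,
             units = 5, age = 12L, brood = 6L, rain = 8, hours = 2.5))
  do.call(rbind, c(n1d1, n1d2, n2d1, n2d2))
}

fixture_vd <- function() as_visit_data(fixture_items())

# Single-nest dataset where day d delivers worm_counts[d] worms (6 cm each)
# in a single visit over hours[d] recorded hours.
rate_fixture <- function(worm_counts, hours = rep(1, length(worm_counts)),
                         brood = 5L, nest_id = "nest1") {
  rows <- list()
  for (d in seq_along(worm_counts)) {
    date <- as.character(as.Date("2012-06-01") + d - 1)
    for (w in seq_len(worm_counts[d])) {
      rows[[length(rows) + 1L]] <- flat_row(
        nest_id = nest_id, date = date, session_order = d, age = d,
        brood = brood, hours = hours[d])
    }
  }
  as_visit_data(do.call(rbind, rows))
}

visit_cols_for_tests <- function() {
  c("nest_id", "date", "session_order", "visit_order", "clock_time",
    "inter_visit_interval_min", "taxon", "is_earthworm",
    "length_beak_units", "n_sundered_pieces", "nestling_age_days",
    "brood_size", "rainfall_mm", "recorded_hours_day")
}

# Independent combinatorial oracle for the two-sided Fisher exact test:
# enumerates all tables with the observed margins via binomial coefficients.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(n, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Piecewise closed-form oracle for the availability-integrated band
# overlap: cuts the domain at every band/observed-edge crossing and
# integrates C + D/a terms analytically on each piece.
overlap_analytic_oracle <- function(worms, observed_band,
                                    density_low = 0.53, density_high = 8.7,
                                    dom = c(0.005, 0.05)) {
  L <- observed_band[1]; U <- observed_band[2]
  n_lo <- worms / density_high  # lower band edge numerator
  n_hi <- worms / density_low   # upper band edge numerator
  cuts <- c(dom, n_lo / L, n_lo / U, n_hi / L, n_hi / U)
  cuts <- sort(unique(pmin(pmax(cuts, dom[1]), dom[2])))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    a0 <- cuts[i]; a1 <- cuts[i + 1L]; am <- (a0 + a1) / 2
    lo <- max(L, n_lo / am); hi <- min(U, n_hi / am)
    if (hi <= lo) next
    int_hi <- if (U < n_hi / am) U * (a1 - a0) else n_hi * log(a1 / a0)
    int_lo <- if (L > n_lo / am) L * (a1 - a0) else n_lo * log(a1 / a0)
    total <- total + (int_hi - int_lo)
  }
  total
}
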