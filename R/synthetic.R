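# Seeded synthetic feeding-visit generator.
#
# The generator emulates the statistical structure of a four-nest
# nest-observation study: per-session visit sequences driven by a gamma
# renewal process, age-conditional visit-type mixtures, truncated binomial
# prey counts, and lognormal prey lengths quantised to 0.5 cm with a
# negative count-length coupling chosen so expected food-load biomass is
# approximately flat in the number of worms carried.

#' Configuration for the synthetic feeding-visit generator
#'
#' Defaults encode the marginal statistics the generator targets: overall
#' visit-type shares 0.648 (OnlyE) / 0.305 (MIX) / 0.047 (NoE) with NoE and
#' MIX enriched for old broods; inter-visit intervals with a visit-weighted
#' marginal mean of 35 min and SD of about 26 min, shortened in the morning
#' and for old broods; 1-6 worms per earthworm-only load (marginal mean
#' 2.6, fewer under heavy rain); 2-7 items per mixed load (mean 3.4);
#' single-item loads for visits without earthworms; earthworm lengths
#' quantised to 0.5 cm with worm-level mean 6.34 cm, SD about 2.5 cm, cap
#' 15.5 cm, shifted upward under heavy rain and downward with worm count
#' (exponent ~ 1/3.19, the inverse allometric slope, so expected load
#' biomass does not grow with count); non-earthworm lengths with mean
#' 3.59 cm.
#'
#' The base interval mean and the base length meanlog are calibrated
#' analytically at configuration time from the discrete count and rain
#' distributions, so the visit-weighted marginal interval mean and the
#' worm-level marginal length mean hit their targets without simulation.
#'
#' @param n_nests Number of nests.
#' @param brood_sizes Integer brood size per nest (3-6).
#' @param young_days,old_days Observation days sampled per nest from the
#'   young (1-7 d) and old (8-13 d) age classes.
#' @param young_ages,old_ages Candidate nestling ages for observation days.
#' @param hours_range Range (h) of daily recorded observation hours.
#' @param heavy_rain_day_probability Probability an observation day is a
#'   heavy-rain day (> 4 mm).
#' @param visit_type_probs 2x3 matrix (rows young/old, columns
#'   NoE/OnlyE/MIX) of visit-type probabilities conditional on age class.
#' @param interval_target_mean_min,interval_cv Target visit-weighted
#'   marginal mean (min) and fixed coefficient of variation of inter-visit
#'   intervals.
#' @param morning_interval_factor,old_interval_factor Multiplicative
#'   reductions of the interval mean in the morning and for old broods.
#' @param onlye_worms_prob Success probabilities (light, heavy rain) of the
#'   shifted binomial 1 + Binom(5, q) for worms per earthworm-only load.
#' @param mix_items_prob Success probability of 2 + Binom(5, q) items per
#'   mixed load.
#' @param mix_worm_prob Per-slot probability that an extra slot of a mixed
#'   load holds a worm (worms = 1 + Binom(items - 2, q)).
#' @param worm_length_mean_cm,worm_length_sdlog Target worm-level marginal
#'   mean length (cm) and lognormal sdlog.
#' @param worm_count_exponent Exponent of the count-length coupling
#'   (lengths scale as count^-exponent).
#' @param worm_rain_lnshift Additive meanlog shift for heavy-rain days.
#' @param other_length_mean_cm,other_length_sdlog Lognormal parameters for
#'   non-earthworm prey lengths.
#' @param max_length_cm Length cap after quantisation.
#' @param unmeasured_prob Probability a worm's length is unmeasured.
#' @param unknown_taxon_prob Probability a non-earthworm item is recorded
#'   as taxon "unknown".
#' @param sunder_threshold_cm Worms at least this long are carried sundered.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nests = 4L,
                             brood_sizes = c(5L, 5L, 6L, 5L),
                             young_days = 4L, old_days = 3L,
                             young_ages = 2:7, old_ages = 8:12,
                             hours_range = c(3, 5),
                             heavy_rain_day_probability = 0.3,
                             visit_type_probs = rbind(
                               young = c(NoE = 0.020, OnlyE = 0.750, MIX = 0.230),
                               old   = c(NoE = 0.074, OnlyE = 0.546, MIX = 0.380)),
                             interval_target_mean_min = 35,
                             interval_cv = 0.743,
                             morning_interval_factor = 0.8,
                             old_interval_factor = 0.85,
                             onlye_worms_prob = c(light = 0.35, heavy = 0.25),
                             mix_items_prob = 0.28,
                             mix_worm_prob = 0.5,
                             worm_length_mean_cm = 6.34,
                             worm_length_sdlog = 0.38,
                             worm_count_exponent = 0.31,
                             worm_rain_lnshift = 0.12,
                             other_length_mean_cm = 3.59,
                             other_length_sdlog = 0.608,
                             max_length_cm = 15.5,
                             unmeasured_prob = 0.02,
                             unknown_taxon_prob = 0.045,
                             sunder_threshold_cm = 8) {
  cfg <- list(
    n_nests = as.integer(n_nests), brood_sizes = as.integer(brood_sizes),
    young_days = as.integer(young_days), old_days = as.integer(old_days),
    young_ages = as.integer(young_ages), old_ages = as.integer(old_ages),
    hours_range = hours_range,
    heavy_rain_day_probability = heavy_rain_day_probability,
    visit_type_probs = visit_type_probs,
    interval_target_mean_min = interval_target_mean_min,
    interval_cv = interval_cv,
    morning_interval_factor = morning_interval_factor,
    old_interval_factor = old_interval_factor,
    onlye_worms_prob = onlye_worms_prob,
    mix_items_prob = mix_items_prob, mix_worm_prob = mix_worm_prob,
    worm_length_mean_cm = worm_length_mean_cm,
    worm_length_sdlog = worm_length_sdlog,
    worm_count_exponent = worm_count_exponent,
    worm_rain_lnshift = worm_rain_lnshift,
    other_length_mean_cm = other_length_mean_cm,
    other_length_sdlog = other_length_sdlog,
    max_length_cm = max_length_cm,
    unmeasured_prob = unmeasured_prob,
    unknown_taxon_prob = unknown_taxon_prob,
    sunder_threshold_cm = sunder_threshold_cm,
    other_taxa_weights = c(
      "centipede" = 0.32, "caterpillar" = 0.12, "beetle" = 0.11,
      "insect pupa" = 0.08, "grasshopper" = 0.08, "moth" = 0.06,
      "mole cricket" = 0.05, "dragonfly" = 0.04, "arrowhead flatworm" = 0.04,
      "stick insect" = 0.03, "snake" = 0.01,
      "unidentifiable arthropod" = 0.04, "unidentifiable non-earthworm" = 0.02)
  )
  validate_synthetic_config(cfg)

  # --- analytic calibrations (no simulation involved) -----------------
  # expected visit weight of each age class: days x visits/session, the
  # latter inversely proportional to the class interval factor
  w_young <- cfg$young_days
  w_old <- cfg$old_days / cfg$old_interval_factor
  cfg$age_class_visit_weights <- c(young = w_young, old = w_old) /
    (w_young + w_old)
  p_type <- drop(cfg$age_class_visit_weights %*% cfg$visit_type_probs)

  # base interval mean: visits sample strata inversely to their mean, so
  # the visit-weighted marginal mean is base * sum(frac) / sum(frac / f)
  morning_frac <- 0.2  # 2 of the 10 observable hours
  frac <- outer(c(cfg$age_class_visit_weights["young"],
                  cfg$age_class_visit_weights["old"]),
                c(morning = morning_frac, rest = 1 - morning_frac))
  fct <- rbind(c(cfg$morning_interval_factor, 1),
               c(cfg$morning_interval_factor * cfg$old_interval_factor,
                 cfg$old_interval_factor))
  cfg$interval_base_mean_min <-
    cfg$interval_target_mean_min * sum(frac / fct) / sum(frac)

  # worm-level joint distribution of (rain, count) across OnlyE and MIX
  # visits, used to centre the length model on the target marginal mean
  p_h <- cfg$heavy_rain_day_probability
  k <- 1:6
  rows <- list()
  for (rain in c("light", "heavy")) {
    q <- cfg$onlye_worms_prob[[rain]]
    p_rain <- if (rain == "heavy") p_h else 1 - p_h
    rows[[paste0("O", rain)]] <- data.frame(
      heavy = rain == "heavy", k = k,
      w = p_type[["OnlyE"]] * p_rain * stats::dbinom(k - 1, 5, q) * k)
    # MIX worm count: 1 + Binom(items - 2, q_w), items = 2 + Binom(5, q_i)
    pk <- vapply(k, function(kk) {
      sum(vapply(2:7, function(items) {
        stats::dbinom(items - 2, 5, cfg$mix_items_prob) *
          stats::dbinom(kk - 1, items - 2, cfg$mix_worm_prob)
      }, 0))
    }, 0)
    rows[[paste0("M", rain)]] <- data.frame(
      heavy = rain == "heavy", k = k,
      w = p_type[["MIX"]] * p_rain * pk * k)
  }
  joint <- do.call(rbind, rows)
  corr <- sum(joint$w * exp(cfg$worm_rain_lnshift * joint$heavy) *
                joint$k^(-cfg$worm_count_exponent)) / sum(joint$w)
  cfg$worm_length_base_meanlog <- log(cfg$worm_length_mean_cm) -
    cfg$worm_length_sdlog^2 / 2 - log(corr)
  cfg$other_length_meanlog <- log(cfg$other_length_mean_cm) -
    cfg$other_length_sdlog^2 / 2

  cfg$targets <- list(
    share_NoE = 0.047, share_OnlyE = 0.648, share_MIX = 0.305,
    interval_mean = 35, interval_sd = 26,
    worms_per_onlye = 2.6, items_per_mix = 3.4,
    worm_length_mean = cfg$worm_length_mean_cm,
    other_length_mean = cfg$other_length_mean_cm)

  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$heavy_rain_day_probability, cfg$onlye_worms_prob,
             cfg$mix_items_prob, cfg$mix_worm_prob, cfg$unmeasured_prob,
             cfg$unknown_taxon_prob, c(cfg$visit_type_probs))
  if (any(probs < 0 | probs > 1)) {
    stop("infeasible config: probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(cfg$visit_type_probs) - 1) > 1e-8)) {
    stop("infeasible config: visit-type probabilities must sum to 1 per age class")
  }
  if (cfg$n_nests < 1L || length(cfg$brood_sizes) != cfg$n_nests ||
      any(cfg$brood_sizes < 3L | cfg$brood_sizes > 6L)) {
    stop("infeasible config: need one brood size (3-6) per nest")
  }
  if (cfg$young_days > length(cfg$young_ages) ||
      cfg$old_days > length(cfg$old_ages) ||
      cfg$young_days < 1L || cfg$old_days < 1L) {
    stop("infeasible config: observation days per age class exceed candidate ages")
  }
  if (cfg$worm_length_mean_cm <= 0.5 ||
      cfg$worm_length_mean_cm >= cfg$max_length_cm) {
    stop("infeasible config: worm length mean outside the quantised support")
  }
  if (cfg$interval_target_mean_min <= 0 || cfg$interval_cv <= 0 ||
      any(cfg$hours_range <= 0) || diff(cfg$hours_range) < 0 ||
      cfg$hours_range[2] > 10) {
    stop("infeasible config: invalid interval or observation-hour settings")
  }
  invisible(cfg)
}

quantize_length_cm <- function(length_cm, max_length_cm) {
  units <- round(length_cm / 0.5) * 0.25
  pmin(pmax(units, 0.25), max_length_cm / 2)
}

draw_worm_lengths <- function(n_worms, heavy, cfg) {
  lnL <- cfg$worm_length_base_meanlog +
    cfg$worm_rain_lnshift * heavy -
    cfg$worm_count_exponent * log(n_worms) +
    stats::rnorm(n_worms, 0, cfg$worm_length_sdlog)
  quantize_length_cm(exp(lnL), cfg$max_length_cm)
}

draw_other_items <- function(n, cfg) {
  taxa <- sample(names(cfg$other_taxa_weights), n, replace = TRUE,
                 prob = cfg$other_taxa_weights)
  unknown <- stats::runif(n) < cfg$unknown_taxon_prob
  taxa[unknown] <- "unknown"
  lnL <- stats::rnorm(n, cfg$other_length_meanlog, cfg$other_length_sdlog)
  list(taxon = taxa,
       units = quantize_length_cm(exp(lnL), cfg$max_length_cm))
}

#' Generate a synthetic feeding-visit dataset
#'
#' Draws a complete, validated dataset under a [synthetic_config()]. One
#' dataset-level stream is seeded from `seed`; per-nest substreams are
#' derived deterministically from it, so identical seed and configuration
#' reproduce the dataset exactly.
#'
#' @param config A `synthetic_config` object.
#' @param seed Integer seed.
#' @return A `visit_data` object (see [as_visit_data()]).
#' @export
#' @examples
#' vd <- generate_visits(synthetic_config(), seed = 1)
#' vd
generate_visits <- function(config = synthetic_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("an explicit seed is required")
  cfg <- config
  set.seed(as.integer(seed))
  nest_seeds <- sample.int(.Machine$integer.max, cfg$n_nests)
  years <- rep(c(2012L, 2013L, 2017L), length.out = cfg$n_nests)

  out <- vector("list", cfg$n_nests)
  for (nest in seq_len(cfg$n_nests)) {
    set.seed(nest_seeds[nest])
    out[[nest]] <- generate_nest(cfg, nest_id = sprintf("nest%d", nest),
                                 brood_size = cfg$brood_sizes[nest],
                                 hatch_date = as.Date(sprintf(
                                   "%d-05-%02d", years[nest], 10 + nest)))
  }
  as_visit_data(do.call(rbind, out))
}

generate_nest <- function(cfg, nest_id, brood_size, hatch_date) {
  ages <- c(sort(sample(cfg$young_ages, cfg$young_days)),
            sort(sample(cfg$old_ages, cfg$old_days)))
  shape <- 1 / cfg$interval_cv^2
  rows <- list()
  for (s in seq_along(ages)) {
    age <- ages[s]
    old <- age >= 8L
    date <- hatch_date + age - 1L
    rain_heavy <- stats::runif(1) < cfg$heavy_rain_day_probability
    rainfall <- if (rain_heavy) round(4.1 + stats::rexp(1, 1 / 6), 1) else
      round(stats::runif(1, 0, 3.9), 1)
    probs <- cfg$visit_type_probs[if (old) "old" else "young", ]

    # a session is bounded by its first and last observed visit: pick a
    # target duration, fix the number of inter-visit gaps it implies, keep
    # every drawn gap, and derive the recorded hours from the visit span
    target_h <- stats::runif(1, cfg$hours_range[1], cfg$hours_range[2])
    mu_class <- cfg$interval_base_mean_min *
      (if (old) cfg$old_interval_factor else 1)
    n_gaps <- max(1L, round(target_h * 60 / mu_class))
    start <- stats::runif(1, 8, max(8.05, 18 - target_h - 1.2))

    t_cur <- start
    interval <- NA_real_
    visit_rows <- list()
    for (order in seq_len(n_gaps + 1L)) {
      visit <- sample_visit_items(cfg, probs, rain_heavy)
      n <- length(visit$taxon)
      visit_rows[[order]] <- data.frame(
        nest_id = nest_id, date = as.character(date),
        session_order = s, visit_order = order,
        clock_time = sprintf("%02d:%02d", floor(t_cur),
                             floor((t_cur - floor(t_cur)) * 60)),
        inter_visit_interval_min = rep(interval, n),
        taxon = visit$taxon, is_earthworm = as.integer(visit$is_worm),
        length_beak_units = visit$units,
        n_sundered_pieces = visit$pieces,
        nestling_age_days = age, brood_size = brood_size,
        rainfall_mm = rainfall, recorded_hours_day = NA_real_,
        stringsAsFactors = FALSE)
      if (order > n_gaps) break
      mu <- cfg$interval_base_mean_min *
        (if (t_cur < 10) cfg$morning_interval_factor else 1) *
        (if (old) cfg$old_interval_factor else 1)
      gap <- round(max(stats::rgamma(1, shape, shape / mu), 0.5), 1)
      if (t_cur + gap / 60 > 17.95) break
      t_cur <- t_cur + gap / 60
      interval <- gap
    }
    session <- do.call(rbind, visit_rows)
    session$recorded_hours_day <- max(round(t_cur - start, 2), 0.25)
    rows[[length(rows) + 1L]] <- session
  }
  do.call(rbind, rows)
}

sample_visit_items <- function(cfg, type_probs, rain_heavy) {
  type <- sample(c("NoE", "OnlyE", "MIX"), 1, prob = type_probs)
  if (type == "NoE") {
    oth <- draw_other_items(1L, cfg)
    return(list(taxon = oth$taxon, is_worm = FALSE, units = oth$units,
                pieces = 1L))
  }
  if (type == "OnlyE") {
    q <- cfg$onlye_worms_prob[[if (rain_heavy) "heavy" else "light"]]
    k <- 1L + stats::rbinom(1, 5, q)
    n_other <- 0L
  } else {
    n_items <- 2L + stats::rbinom(1, 5, cfg$mix_items_prob)
    k <- 1L + stats::rbinom(1, n_items - 2L, cfg$mix_worm_prob)
    n_other <- n_items - k
  }
  units <- draw_worm_lengths(k, rain_heavy, cfg)
  cm <- units * 2
  pieces <- ifelse(cm >= cfg$sunder_threshold_cm, pmax(2L, round(cm / 4)), 1L)
  units[stats::runif(k) < cfg$unmeasured_prob] <- NA_real_
  taxon <- rep("earthworm", k)
  is_worm <- rep(TRUE, k)
  if (n_other > 0L) {
    oth <- draw_other_items(n_other, cfg)
    taxon <- c(taxon, oth$taxon)
    is_worm <- c(is_worm, rep(FALSE, n_other))
    units <- c(units, oth$units)
    pieces <- c(pieces, rep(1L, n_other))
  }
  list(taxon = taxon, is_worm = is_worm, units = units, pieces = pieces)
}

#' Compare a generated dataset against its configuration targets
#'
#' Computes empirical marginals (visit-type shares, inter-visit interval
#' mean and SD after excluding first visits, prey counts per load, worm and
#' other prey length means) side by side with the generator targets, with
#' Monte-Carlo tolerances of three standard errors plus a small allowance
#' for the model's analytic approximations. Rain-effect directions (fewer
#' worms per earthworm-only load and heavier single worms under heavy rain)
#' are reported as signed contrasts whose expected direction must hold at
#' large sample sizes.
#'
#' @param vd A `visit_data` object produced by [generate_visits()].
#' @param config The `synthetic_config` used to generate it.
#' @return Data frame with columns `statistic`, `target`, `empirical`,
#'   `tolerance`, `within`.
#' @export
recovery_report <- function(vd, config) {
  stopifnot(inherits(vd, "visit_data"), inherits(config, "synthetic_config"))
  tg <- config$targets
  visits <- vd$visits
  items <- vd$items
  n_vis <- nrow(visits)
  rows <- list()
  add <- function(statistic, target, empirical, tolerance) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, target = target, empirical = empirical,
      tolerance = tolerance,
      within = is.finite(empirical) && abs(empirical - target) <= tolerance)
  }

  shares <- prop.table(table(visits$visit_type))
  for (ty in visit_type_levels()) {
    t0 <- tg[[paste0("share_", ty)]]
    add(paste0("share_", ty), t0, as.numeric(shares[[ty]]),
        3 * sqrt(t0 * (1 - t0) / n_vis) + 0.01)
  }

  iv <- exclude_first_visits(visits)$inter_visit_interval_min
  add("interval_mean", tg$interval_mean, mean(iv),
      3 * stats::sd(iv) / sqrt(length(iv)) + 1.5)
  add("interval_sd", tg$interval_sd, stats::sd(iv),
      3 * stats::sd(iv) / sqrt(2 * length(iv)) + 2)

  only <- visits[visits$visit_type == "OnlyE", ]
  add("worms_per_onlye", tg$worms_per_onlye, mean(only$n_earthworms),
      3 * stats::sd(only$n_earthworms) / sqrt(nrow(only)) + 0.1)
  mix <- visits[visits$visit_type == "MIX", ]
  add("items_per_mix", tg$items_per_mix, mean(mix$n_items),
      3 * stats::sd(mix$n_items) / sqrt(nrow(mix)) + 0.1)

  wl <- items$length_cm[items$is_earthworm == 1L & !is.na(items$length_cm)]
  add("worm_length_mean", tg$worm_length_mean, mean(wl),
      3 * stats::sd(wl) / sqrt(length(wl)) + 0.2)
  ol <- items$length_cm[items$is_earthworm == 0L & !is.na(items$length_cm)]
  add("other_length_mean", tg$other_length_mean, mean(ol),
      3 * stats::sd(ol) / sqrt(length(ol)) + 0.3)

  # rain-effect directions: empirical = heavy-minus-light contrast; the
  # "target" records the expected sign (+1/-1) and within checks it
  dir <- function(statistic, contrast, sign) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, target = sign, empirical = contrast,
      tolerance = NA_real_,
      within = is.finite(contrast) && sign * contrast > 0)
  }
  dir("worms_per_onlye_heavy_minus_light",
      mean(only$n_earthworms[only$rain_category == "heavy"]) -
        mean(only$n_earthworms[only$rain_category == "light"]), -1)
  worm_items <- items[items$is_earthworm == 1L & !is.na(items$length_cm), ]
  afdm <- afdm_from_length(worm_items$length_cm * 10)
  heavy <- categorize_rain(worm_items$rainfall_mm) == "heavy"
  dir("single_worm_afdm_heavy_minus_light",
      mean(afdm[heavy]) - mean(afdm[!heavy]), +1)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
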