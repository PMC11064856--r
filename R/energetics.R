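# Bioenergetic chain: allometric length-to-biomass conversion, daily energy
# expenditure (DEE), and the consumption extrapolation from observed
# provisioning rates to brood, parent and family totals.

#' Constants of the bioenergetic chain
#'
#' Returns the parameter set used throughout the consumption and home-range
#' calculations. Defaults:
#' \describe{
#'   \item{allometry_slope, allometry_intercept}{AFDM (g) =
#'     exp(3.19 ln L(mm) - 15.85), the Megascolecidae length-biomass
#'     allometry.}
#'   \item{fresh_to_afdm_ratio}{5.7904 g fresh per g ash-free dry mass.}
#'   \item{dee_coefficient, dee_exponent}{DEE (kJ/day) = 1092 BM^0.729 with
#'     body mass BM in kilograms.}
#'   \item{male_mass_kg, female_mass_kg}{0.109 and 0.0715 kg adult masses.}
#'   \item{pair_dee_printed}{377 kJ/day, the rounded pair DEE used in the
#'     downstream consumption equation.}
#'   \item{worm_energy_density}{16.72 kJ per g AFDM of earthworm tissue.}
#'   \item{mean_worm_afdm_g}{0.12258 g AFDM per average earthworm.}
#'   \item{provisioning_hours_per_day}{15 h of daily provisioning.}
#'   \item{nestling_period_days, incubation_days, nest_building_days}{12.05,
#'     14 and 10 days; their sum (36.05) is the breeding-event duration for
#'     parental consumption.}
#'   \item{standard_brood_size}{5 nestlings.}
#'   \item{printed_brood_consumption_5}{855 worms consumed by a
#'     standardized brood of five.}
#' }
#'
#' @param ... Named overrides of any default.
#' @return Object of class `energetics_params`.
#' @export
energetics_params <- function(...) {
  p <- list(
    allometry_slope = 3.19, allometry_intercept = -15.85,
    fresh_to_afdm_ratio = 5.7904,
    dee_coefficient = 1092, dee_exponent = 0.729,
    male_mass_kg = 0.109, female_mass_kg = 0.0715,
    pair_dee_printed = 377,
    worm_energy_density = 16.72,
    mean_worm_afdm_g = 0.12258,
    provisioning_hours_per_day = 15,
    nestling_period_days = 12.05,
    incubation_days = 14,
    nest_building_days = 10,
    standard_brood_size = 5,
    printed_brood_consumption_5 = 855
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  numeric_pos <- setdiff(names(p), "allometry_intercept")
  if (any(!vapply(p, is.numeric, TRUE)) ||
      any(vapply(p[numeric_pos], function(x) x <= 0, TRUE))) {
    stop("all energetic parameters must be numeric and positive ",
         "(the allometric intercept excepted)")
  }
  structure(p, class = "energetics_params")
}

breeding_event_days <- function(params) {
  params$nestling_period_days + params$incubation_days +
    params$nest_building_days
}

#' Earthworm ash-free dry mass from length
#'
#' AFDM (g) = exp(slope * ln(length mm) + intercept); strictly increasing
#' in length.
#'
#' @param length_mm Positive length(s) in millimetres.
#' @param params An [energetics_params()] object.
#' @return AFDM in grams.
#' @export
#' @examples
#' afdm_from_length(63.4)  # ~0.0733 g
afdm_from_length <- function(length_mm, params = energetics_params()) {
  if (any(is.na(length_mm)) || any(length_mm <= 0)) {
    stop("length must be positive (mm)")
  }
  exp(params$allometry_slope * log(length_mm) + params$allometry_intercept)
}

#' Fresh mass from ash-free dry mass
#'
#' @param afdm_g Non-negative AFDM in grams.
#' @param params An [energetics_params()] object.
#' @return Fresh mass in grams (AFDM x 5.7904 by default).
#' @export
fresh_from_afdm <- function(afdm_g, params = energetics_params()) {
  if (any(is.na(afdm_g)) || any(afdm_g < 0)) stop("AFDM must be non-negative")
  afdm_g * params$fresh_to_afdm_ratio
}

#' Daily energy expenditure from body mass
#'
#' DEE (kJ/day) = 1092 * BM^0.729 with body mass in kilograms.
#'
#' @param body_mass_kg Positive body mass(es) in kg.
#' @param params An [energetics_params()] object.
#' @return DEE in kJ/day.
#' @export
#' @examples
#' dee(1)      # 1092
#' dee(0.109)  # ~217 kJ/day (adult male)
dee <- function(body_mass_kg, params = energetics_params()) {
  if (any(is.na(body_mass_kg)) || any(body_mass_kg <= 0)) {
    stop("body mass must be positive (kg)")
  }
  params$dee_coefficient * body_mass_kg^params$dee_exponent
}

#' Pair daily energy expenditure
#'
#' Sum of the male and female DEE. With the default masses the unrounded
#' sum is 376.6 kJ/day, reported rounded to the integer 377 used by the
#' downstream consumption equation.
#'
#' @param params An [energetics_params()] object.
#' @param rounded Round to the nearest integer (default) or return the
#'   full-precision sum.
#' @return Pair DEE in kJ/day.
#' @export
pair_dee <- function(params = energetics_params(), rounded = TRUE) {
  total <- dee(params$male_mass_kg, params) +
    dee(params$female_mass_kg, params)
  if (rounded) round_half_up(total) else total
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-day provisioning rates of earthworms
#'
#' For every observation day of every nest: the number of earthworms
#' delivered per recorded hour and the summed worm AFDM per recorded hour.
#' Worms in mixed food-loads count; days with recorded hours but no visits
#' are valid zero-rate days. Worms without a measured length contribute to
#' counts but not to biomass.
#'
#' @param vd A `visit_data` object.
#' @param params An [energetics_params()] object.
#' @param extra_days Optional data frame (`nest_id`, `date`,
#'   `recorded_hours_day`) of observation days without any visit; these are
#'   valid zero-rate days and enter the per-day averages.
#' @return Data frame with one row per nest-day: `nest_id`, `date`,
#'   `recorded_hours`, `n_worms`, `worms_per_hour`, `afdm_g`,
#'   `afdm_g_per_hour`, `n_unmeasured_worms`.
#' @export
daily_rates <- function(vd, params = energetics_params(), extra_days = NULL) {
  stopifnot(inherits(vd, "visit_data"))
  days <- vd$days
  if (!is.null(extra_days)) {
    stopifnot(all(c("nest_id", "date", "recorded_hours_day") %in%
                    names(extra_days)))
    add <- days[0, ]
    add[seq_len(nrow(extra_days)), c("nest_id", "date",
                                     "recorded_hours_day")] <-
      extra_days[, c("nest_id", "date", "recorded_hours_day")]
    days <- rbind(days, add)
  }
  items <- vd$items[vd$items$is_earthworm == 1L, ]
  out <- days[, c("nest_id", "date")]
  out$recorded_hours <- days$recorded_hours_day
  key <- paste(days$nest_id, days$date)
  item_key <- paste(items$nest_id, items$date)
  out$n_worms <- vapply(key, function(k) sum(item_key == k), 0L,
                        USE.NAMES = FALSE)
  out$afdm_g <- vapply(key, function(k) {
    len <- items$length_cm[item_key == k]
    len <- len[!is.na(len)]
    if (length(len) == 0) 0 else sum(afdm_from_length(len * 10, params))
  }, 0, USE.NAMES = FALSE)
  out$n_unmeasured_worms <- vapply(key, function(k) {
    sum(is.na(items$length_cm[item_key == k]))
  }, 0L, USE.NAMES = FALSE)
  zero_hours <- out$recorded_hours <= 0
  if (any(zero_hours)) {
    warning(sum(zero_hours), " day(s) with zero recorded hours excluded")
    out <- out[!zero_hours, ]
  }
  out$worms_per_hour <- out$n_worms / out$recorded_hours
  out$afdm_g_per_hour <- out$afdm_g / out$recorded_hours
  rownames(out) <- NULL
  out
}

#' Brood earthworm consumption over the nestling period
#'
#' Averages each nest's daily worms-per-hour and AFDM-per-hour rates,
#' scales by the daily provisioning hours (15 h) and the nestling-period
#' duration (12.05 days) to a per-brood total, divides by brood size for a
#' per-nestling estimate, and averages per-nestling estimates across the
#' selected nests scaled to a standardized brood of five. The default nest
#' selection drops the nest with the fewest recorded days (ties broken by
#' fewest recorded hours), mirroring the use of the more reliably sampled
#' nests; `nests = "all"` keeps every nest, or pass nest ids.
#'
#' @param vd A `visit_data` object.
#' @param params An [energetics_params()] object.
#' @param nests `"subset"` (default), `"all"`, or a character vector of
#'   nest ids for the standardized-brood average.
#' @return List with `per_nest` (data frame of per-nest totals),
#'   `standardized_brood_worms`, `standardized_brood_afdm_g`,
#'   `standardized_brood_fresh_g`, and `nests_used`.
#' @export
brood_consumption <- function(vd, params = energetics_params(),
                              nests = c("subset", "all")) {
  stopifnot(inherits(vd, "visit_data"))
  if (is.character(nests) && length(nests) > 1L &&
      identical(sort(nests), c("all", "subset"))) {
    nests <- nests[1]
  }
  rates <- daily_rates(vd, params)
  if (nrow(rates) == 0L) stop("no observation days with positive hours")
  scale <- params$provisioning_hours_per_day * params$nestling_period_days

  per_nest <- do.call(rbind, lapply(split(rates, rates$nest_id), function(r) {
    data.frame(nest_id = r$nest_id[1], n_days = nrow(r),
               recorded_hours = sum(r$recorded_hours),
               mean_worms_per_hour = mean(r$worms_per_hour),
               mean_afdm_g_per_hour = mean(r$afdm_g_per_hour))
  }))
  per_nest$brood_worms <- per_nest$mean_worms_per_hour * scale
  per_nest$brood_afdm_g <- per_nest$mean_afdm_g_per_hour * scale
  per_nest$brood_fresh_g <- fresh_from_afdm(per_nest$brood_afdm_g, params)
  bs <- vd$days$brood_size[match(per_nest$nest_id, vd$days$nest_id)]
  per_nest$brood_size <- bs
  per_nest$per_nestling_worms <- per_nest$brood_worms / bs
  per_nest$per_nestling_afdm_g <- per_nest$brood_afdm_g / bs
  rownames(per_nest) <- NULL

  if (is.character(nests) && length(nests) == 1L &&
      nests %in% c("subset", "all")) {
    used <- per_nest$nest_id
    if (nests == "subset" && nrow(per_nest) > 1L) {
      drop_idx <- order(per_nest$n_days, per_nest$recorded_hours)[1]
      used <- per_nest$nest_id[-drop_idx]
    }
  } else {
    used <- as.character(nests)
    if (!all(used %in% per_nest$nest_id)) stop("unknown nest id in selection")
    if (length(used) == 0L) stop("empty nest selection")
  }
  sel <- per_nest[per_nest$nest_id %in% used, ]
  std_worms <- mean(sel$per_nestling_worms) * params$standard_brood_size
  std_afdm <- mean(sel$per_nestling_afdm_g) * params$standard_brood_size
  list(per_nest = per_nest,
       standardized_brood_worms = std_worms,
       standardized_brood_afdm_g = std_afdm,
       standardized_brood_fresh_g = fresh_from_afdm(std_afdm, params),
       nests_used = used)
}

#' Parent earthworm consumption over a breeding event
#'
#' Number of worms needed to cover a proportion `p` of the pair's daily
#' energy expenditure over the whole breeding event (nestling period +
#' incubation + nest building = 36.05 days), at 0.12258 g AFDM and
#' 16.72 kJ/g AFDM per average worm. Uses the printed integer pair DEE
#' (377 kJ/day by default), which is what reproduces the published family
#' totals exactly.
#'
#' @param p Proportion(s) in \[0, 1\] of the adult DEE covered by
#'   earthworms.
#' @param params An [energetics_params()] object.
#' @return Number of worms (full precision; linear in `p`).
#' @export
#' @examples
#' parent_consumption(c(0.3, 0.7))  # ~1989 and ~4642 worms
parent_consumption <- function(p, params = energetics_params()) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("diet proportion p must lie in [0, 1]")
  }
  p * params$pair_dee_printed * breeding_event_days(params) /
    (params$mean_worm_afdm_g * params$worm_energy_density)
}

#' Family earthworm consumption
#'
#' Standardized brood consumption plus parental consumption at diet
#' proportion `p`.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param params An [energetics_params()] object.
#' @param brood_worms Standardized brood consumption in worms; defaults to
#'   the printed 855-worm estimate for a brood of five.
#' @return Number of worms (full precision; round at reporting time).
#' @export
#' @examples
#' round(family_consumption(c(0.3, 0.7)))  # 2844 and 5497
family_consumption <- function(p, params = energetics_params(),
                               brood_worms = params$printed_brood_consumption_5) {
  if (any(is.na(brood_worms)) || any(brood_worms < 0)) {
    stop("brood consumption must be non-negative")
  }
  brood_worms + parent_consumption(p, params)
}

#' Consumption table across diet-proportion scenarios
#'
#' Assembles brood, parent and family consumption (worms, AFDM and fresh
#' biomass) over a grid of earthworm diet proportions. Worm counts are
#' rounded half-up to integers at this reporting step only; biomass is
#' derived from the unrounded counts via the mean worm AFDM and the
#' fresh-mass ratio.
#'
#' @param params An [energetics_params()] object.
#' @param p_grid Diet proportions for the parent/family scenarios.
#' @param brood_worms Standardized brood consumption in worms.
#' @return Data frame with columns `scope`, `p`, `worms`, `afdm_g`,
#'   `fresh_g`.
#' @export
consumption_table <- function(params = energetics_params(),
                              p_grid = seq(0.3, 0.7, by = 0.1),
                              brood_worms = params$printed_brood_consumption_5) {
  worms <- c(brood_worms, parent_consumption(p_grid, params),
             family_consumption(p_grid, params, brood_worms))
  out <- data.frame(
    scope = c("brood", rep("parents", length(p_grid)),
              rep("family", length(p_grid))),
    p = c(NA, p_grid, p_grid),
    worms = round_half_up(worms),
    afdm_g = worms * params$mean_worm_afdm_g)
  out$fresh_g <- fresh_from_afdm(out$afdm_g, params)
  out
}
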