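# Domain categorisation rules for feeding-visit data.
#
# All categorical derivations (visit type, time of day, rain class, nestling
# age class) live here so that every derived column in a visit table can be
# re-derived from the raw fields and checked for idempotence.

#' Taxonomic categories used for prey items
#'
#' The twelve field-identifiable taxa plus the three bookkeeping categories
#' used when identification was not possible. `"unknown"` items are retained
#' in visit tables but excluded from diet-composition denominators.
#'
#' @param identified_only If `TRUE`, return only the twelve identifiable
#'   taxa; otherwise include the unidentifiable/unknown bookkeeping labels.
#' @return Character vector of taxon labels.
#' @export
#' @examples
#' prey_taxa()
prey_taxa <- function(identified_only = FALSE) {
  taxa <- c(
    "earthworm", "centipede", "caterpillar", "beetle", "insect pupa",
    "dragonfly", "arrowhead flatworm", "mole cricket", "moth",
    "grasshopper", "stick insect", "snake"
  )
  if (identified_only) {
    taxa
  } else {
    c(taxa, "unidentifiable arthropod", "unidentifiable non-earthworm",
      "unknown")
  }
}

#' Classify a feeding visit from its prey items
#'
#' A visit is `"NoE"` when no item in the food-load is an earthworm,
#' `"OnlyE"` when every item is, and `"MIX"` otherwise.
#'
#' @param is_earthworm Logical vector, one element per prey item in the
#'   food-load.
#' @return One of `"NoE"`, `"OnlyE"`, `"MIX"`.
#' @export
#' @examples
#' classify_visit(c(TRUE, TRUE, TRUE))   # "OnlyE"
#' classify_visit(c(TRUE, FALSE))        # "MIX"
classify_visit <- function(is_earthworm) {
  if (length(is_earthworm) == 0L) {
    stop("malformed visit: a food-load must contain at least one prey item")
  }
  if (anyNA(is_earthworm) || !is.logical(is_earthworm)) {
    stop("malformed visit: 'is_earthworm' must be logical without NA")
  }
  n_worm <- sum(is_earthworm)
  if (n_worm == 0L) "NoE" else if (n_worm == length(is_earthworm)) "OnlyE" else "MIX"
}

visit_type_levels <- function() c("NoE", "OnlyE", "MIX")

# Parse "HH:MM" (or decimal hours) into decimal hours.
as_decimal_hours <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("unparseable clock time: ", paste(x[bad], collapse = ", "))
  }
  vapply(m, function(p) as.numeric(p[2]) + as.numeric(p[3]) / 60, 0)
}

#' Categorise the time of day of a feeding visit
#'
#' Observation hours span 08:00-18:00. Categories use half-open intervals:
#' morning \[8, 10), noon \[10, 14), afternoon \[14, 18\]. A boundary time
#' such as 10:00 therefore falls into the later category; the last instant
#' of the window (18:00) is afternoon.
#'
#' @param clock_time Character `"HH:MM"` or numeric decimal hours.
#' @return Factor with levels morning, noon, afternoon.
#' @export
#' @examples
#' categorize_time(c("09:30", "10:00", "17:59"))
categorize_time <- function(clock_time) {
  h <- as_decimal_hours(clock_time)
  if (any(h < 8 | h > 18)) {
    stop("clock time out of observation window (08:00-18:00): ",
         paste(clock_time[h < 8 | h > 18], collapse = ", "))
  }
  out <- ifelse(h < 10, "morning", ifelse(h < 14, "noon", "afternoon"))
  factor(out, levels = c("morning", "noon", "afternoon"))
}

#' Categorise daily rainfall
#'
#' Days with cumulative precipitation exceeding 4 mm are "heavy" rain days;
#' 4 mm or less (including dry days) are "light". The boundary value of
#' exactly 4 mm is light, since heavy requires precipitation to exceed
#' 4 mm/day.
#'
#' @param rainfall_mm Non-negative numeric, daily cumulative rainfall in mm.
#' @return Factor with levels light, heavy.
#' @export
#' @examples
#' categorize_rain(c(0, 4, 12.5))
categorize_rain <- function(rainfall_mm) {
  if (any(is.na(rainfall_mm)) || any(rainfall_mm < 0)) {
    stop("rainfall must be non-negative and non-missing")
  }
  factor(ifelse(rainfall_mm > 4, "heavy", "light"),
         levels = c("light", "heavy"))
}

#' Categorise nestling age into the two brood age classes
#'
#' Broods of 1-7 days are "young", 8-13 days are "old".
#'
#' @param nestling_age_days Integer vector of ages in days (1-13).
#' @return Factor with levels young, old.
#' @export
#' @examples
#' categorize_age(c(1, 7, 8))
categorize_age <- function(nestling_age_days) {
  a <- nestling_age_days
  if (any(is.na(a)) || any(a != round(a)) || any(a < 1 | a > 13)) {
    stop("nestling age must be an integer between 1 and 13 days")
  }
  factor(ifelse(a <= 7, "young", "old"), levels = c("young", "old"))
}

#' Convert prey length from beak units to centimetres
#'
#' Prey lengths are estimated from photographs in units of beak length, to
#' the nearest 0.25 beak length, and converted assuming a beak length of
#' 2 cm. Lengths are therefore quantised to 0.5 cm steps.
#'
#' @param length_beak_units Positive numeric, multiples of 0.25.
#' @return Length in cm.
#' @export
#' @examples
#' beak_units_to_cm(c(0.25, 3.25, 7.75))  # 0.5, 6.5, 15.5 cm
beak_units_to_cm <- function(length_beak_units) {
  u <- length_beak_units
  if (any(is.na(u)) || any(u <= 0)) {
    stop("length in beak units must be positive and non-missing")
  }
  if (any(abs(u / 0.25 - round(u / 0.25)) > 1e-8)) {
    stop("length in beak units must be quantised to multiples of 0.25")
  }
  u * 2
}

#' Drop the first visit of every observation session
#'
#' The inter-visit interval preceding the first visit of a session (one
#' nest-day) cannot be evaluated, so interval-based analyses use the visit
#' table with exactly the first visit of each session removed.
#'
#' @param visits A visit-level data frame carrying `session_id` and
#'   `visit_order` columns (e.g. the `visits` element of a
#'   [visit_data] object).
#' @return The visit table without the first visit of each session.
#' @export
exclude_first_visits <- function(visits) {
  stopifnot(is.data.frame(visits),
            all(c("session_id", "visit_order") %in% names(visits)))
  if (nrow(visits) == 0L) return(visits)
  first <- stats::ave(visits$visit_order, visits$session_id, FUN = min)
  visits[visits$visit_order != first, , drop = FALSE]
}
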