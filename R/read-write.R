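# Readers, writers and the visit_data container.
#
# The on-disk interchange format is a UTF-8 CSV with one row per prey item;
# the in-memory container derives item-, visit- and day-level views from it.

#' Column schema of the feeding-visit CSV interchange format
#'
#' One row per prey item. `inter_visit_interval_min` is blank for the
#' first visit of a session, `length_beak_units` is blank when a prey
#' item could not be measured; `date` is ISO-8601 and `clock_time` is
#' `HH:MM`.
#'
#' @return Character vector of mandatory column names, in canonical order.
#' @export
visit_csv_columns <- function() {
  c("nest_id", "date", "session_order", "visit_order", "clock_time",
    "inter_visit_interval_min", "taxon", "is_earthworm",
    "length_beak_units", "n_sundered_pieces", "nestling_age_days",
    "brood_size", "rainfall_mm", "recorded_hours_day")
}

num_or_na <- function(x, what, rows) {
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable %s at row(s) %s", what,
                 paste(rows[bad], collapse = ", ")))
  }
  out
}

#' Build a typed visit dataset from a flat prey-item table
#'
#' Validates a one-row-per-prey-item table against the documented column
#' schema, derives all typed fields (length in cm, visit type, time-of-day,
#' rain and age categories), and assembles the three coordinated views used
#' throughout the package: `items` (one row per prey item), `visits` (one
#' row per feeding visit) and `days` (one row per nest observation day,
#' carrying recorded hours and rainfall). A validation summary records how
#' many items are unmeasured or of unknown taxon; such rows are retained but
#' excluded from the relevant summary denominators downstream.
#'
#' @param items Data frame with the columns of [visit_csv_columns()].
#' @return An object of class `visit_data`: a list with elements `items`,
#'   `visits`, `days` and `validation`.
#' @export
as_visit_data <- function(items) {
  stopifnot(is.data.frame(items))
  missing_cols <- setdiff(visit_csv_columns(), names(items))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  items <- items[visit_csv_columns()]
  rows <- seq_len(nrow(items))

  items$nest_id <- as.character(items$nest_id)
  items$date <- as.character(items$date)
  items$taxon <- as.character(items$taxon)
  bad_taxon <- !items$taxon %in% prey_taxa()
  if (any(bad_taxon)) {
    stop("unknown taxon label at row(s) ",
         paste(rows[bad_taxon], collapse = ", "))
  }
  for (col in c("session_order", "visit_order", "is_earthworm",
                "n_sundered_pieces", "nestling_age_days", "brood_size")) {
    items[[col]] <- as.integer(num_or_na(as.character(items[[col]]), col, rows))
  }
  for (col in c("inter_visit_interval_min", "length_beak_units",
                "rainfall_mm", "recorded_hours_day")) {
    items[[col]] <- num_or_na(as.character(items[[col]]), col, rows)
  }
  items$clock_time <- as.character(items$clock_time)

  if (any(is.na(items$is_earthworm)) || !all(items$is_earthworm %in% 0:1)) {
    stop("is_earthworm must be 0 or 1 for every row")
  }
  worm_flag <- items$is_earthworm == 1L
  if (any(worm_flag & items$taxon != "earthworm")) {
    stop("is_earthworm = 1 requires taxon 'earthworm' (rows ",
         paste(rows[worm_flag & items$taxon != "earthworm"], collapse = ", "),
         ")")
  }
  if (any(items$taxon == "earthworm" & !worm_flag)) {
    stop("taxon 'earthworm' requires is_earthworm = 1")
  }
  if (any(is.na(items$n_sundered_pieces)) || any(items$n_sundered_pieces < 1)) {
    stop("n_sundered_pieces must be a positive integer")
  }

  measured <- !is.na(items$length_beak_units)
  if (any(measured)) beak_units_to_cm(items$length_beak_units[measured])
  items$length_cm <- ifelse(measured, items$length_beak_units * 2, NA_real_)

  items$session_id <- paste(items$nest_id, items$date, sep = "/")
  items$visit_id <- paste(items$session_id, items$visit_order, sep = "/")
  items$item_id <- paste(items$visit_id, stats::ave(rows, items$visit_id,
                                                    FUN = seq_along),
                         sep = "/")

  # visit-level view: per-visit fields must be constant within a visit
  idx <- !duplicated(items$visit_id)
  per_visit_cols <- c("nest_id", "session_id", "date", "session_order",
                      "visit_order", "clock_time",
                      "inter_visit_interval_min", "nestling_age_days",
                      "brood_size", "rainfall_mm", "recorded_hours_day")
  for (col in per_visit_cols) {
    n_distinct <- tapply(items[[col]], items$visit_id,
                         function(v) length(unique(v[!is.na(v)])))
    if (any(n_distinct > 1)) {
      stop("column '", col, "' is not constant within visit(s) ",
           paste(names(n_distinct)[n_distinct > 1], collapse = ", "))
    }
  }
  visits <- items[idx, c("visit_id", per_visit_cols)]
  rownames(visits) <- NULL
  counts <- table(items$visit_id)
  visits$n_items <- as.integer(counts[visits$visit_id])
  worm_counts <- tapply(worm_flag, items$visit_id, sum)
  visits$n_earthworms <- as.integer(worm_counts[visits$visit_id])
  visits$visit_type <- factor(
    ifelse(visits$n_earthworms == 0L, "NoE",
           ifelse(visits$n_earthworms == visits$n_items, "OnlyE", "MIX")),
    levels = visit_type_levels())
  visits$time_of_day <- categorize_time(visits$clock_time)
  visits$rain_category <- categorize_rain(visits$rainfall_mm)
  visits$age_class <- categorize_age(visits$nestling_age_days)
  visits <- visits[order(visits$nest_id, visits$date, visits$visit_order), ]
  rownames(visits) <- NULL

  first <- stats::ave(visits$visit_order, visits$session_id, FUN = min)
  if (any(!is.na(visits$inter_visit_interval_min[visits$visit_order == first]))) {
    stop("the first visit of a session must not carry an inter-visit interval")
  }
  later <- visits$visit_order != first
  if (any(is.na(visits$inter_visit_interval_min[later]))) {
    stop("non-first visits must carry a positive inter-visit interval")
  }
  if (any(visits$inter_visit_interval_min[later] <= 0)) {
    stop("inter-visit intervals must be positive")
  }

  days <- visits[!duplicated(visits$session_id),
                 c("session_id", "nest_id", "date", "session_order",
                   "nestling_age_days", "brood_size", "rainfall_mm",
                   "recorded_hours_day")]
  rownames(days) <- NULL
  if (any(is.na(days$recorded_hours_day)) || any(days$recorded_hours_day <= 0)) {
    stop("recorded_hours_day must be positive for every observation day")
  }
  age_step <- tapply(days$nestling_age_days, days$nest_id,
                     function(a) all(diff(sort(a)) >= 1))
  if (!all(unlist(age_step))) {
    stop("nestling ages must increase with observation date within a nest")
  }

  validation <- list(
    n_items = nrow(items),
    n_visits = nrow(visits),
    n_sessions = nrow(days),
    n_nests = length(unique(items$nest_id)),
    n_unknown_taxon = sum(items$taxon == "unknown"),
    n_unmeasured = sum(!measured),
    notes = c(
      "items with taxon 'unknown' are retained but excluded from diet-composition denominators",
      "items without a measured length are retained but excluded from length summaries"
    )
  )

  structure(list(items = items, visits = visits, days = days,
                 validation = validation),
            class = "visit_data")
}

#' Read a feeding-visit table from CSV
#'
#' Reads a delimited one-row-per-prey-item table (see
#' [visit_csv_columns()] for the schema), validates it and returns the
#' typed [as_visit_data()] container. Parse failures report the offending
#' row numbers.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A `visit_data` object.
#' @export
read_visits <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_visit_data(raw)
}

#' Write a visit dataset to CSV
#'
#' Writes the flat one-row-per-prey-item table; a write/read round trip is
#' lossless for all typed fields.
#'
#' @param vd A `visit_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(vd, path) {
  stopifnot(inherits(vd, "visit_data"))
  utils::write.csv(vd$items[visit_csv_columns()], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.visit_data <- function(x, ...) {
  v <- x$validation
  cat("Feeding-visit dataset:", v$n_items, "prey items in", v$n_visits,
      "visits,\n  ", v$n_sessions, "observation sessions across", v$n_nests,
      "nests\n")
  cat("  visit types:",
      paste(sprintf("%s=%d", levels(x$visits$visit_type),
                    tabulate(x$visits$visit_type, 3L)), collapse = ", "),
      "\n")
  cat("  unknown-taxon items:", v$n_unknown_taxon,
      "| unmeasured lengths:", v$n_unmeasured, "\n")
  invisible(x)
}

#' Validation summary of a visit dataset
#'
#' @param vd A `visit_data` object.
#' @param json_path Optional path; when given, the summary is also written
#'   as JSON.
#' @return The validation list, invisibly when writing.
#' @export
validation_report <- function(vd, json_path = NULL) {
  stopifnot(inherits(vd, "visit_data"))
  if (!is.null(json_path)) {
    jsonlite::write_json(vd$validation, json_path, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(vd$validation))
  }
  vd$validation
}
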