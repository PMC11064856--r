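# Diet composition, prey-length summaries, visit-type proportions, and the
# contingency-table statistics (per-nest Fisher exact tests combined by
# Fisher's method).

#' Diet composition over identified prey items
#'
#' Counts and percentages per taxon over all items whose taxon could be
#' identified; items recorded as `"unknown"` are excluded from the
#' denominator and reported separately.
#'
#' @param vd A `visit_data` object, or an item-level data frame with
#'   a `taxon` column.
#' @return Data frame with columns `taxon`, `count`, `percent` (one
#'   decimal), sorted by decreasing count; attributes `n_identified` and
#'   `n_unknown`.
#' @export
composition <- function(vd) {
  items <- if (inherits(vd, "visit_data")) vd$items else vd
  stopifnot(is.data.frame(items), "taxon" %in% names(items))
  if (nrow(items) == 0L) stop("no prey items to summarise")
  known <- items$taxon[items$taxon != "unknown"]
  counts <- sort(table(known), decreasing = TRUE)
  out <- data.frame(taxon = names(counts), count = as.integer(counts),
                    percent = round(100 * as.integer(counts) / length(known), 1),
                    row.names = NULL)
  attr(out, "n_identified") <- length(known)
  attr(out, "n_unknown") <- sum(items$taxon == "unknown")
  out
}

#' Visit-type counts and proportions
#'
#' Shares of NoE / OnlyE / MIX visits, plus the derived YesE share
#' (OnlyE and MIX combined), with raw counts.
#'
#' @param vd A `visit_data` object, or a visit-level data frame with a
#'   `visit_type` column.
#' @return Data frame with columns `visit_type`, `count`, `percent` (one
#'   decimal).
#' @export
visit_type_proportions <- function(vd) {
  visits <- if (inherits(vd, "visit_data")) vd$visits else vd
  stopifnot(is.data.frame(visits), "visit_type" %in% names(visits))
  n <- nrow(visits)
  counts <- table(factor(visits$visit_type, levels = visit_type_levels()))
  yes_e <- sum(counts[c("OnlyE", "MIX")])
  data.frame(
    visit_type = c(visit_type_levels(), "YesE"),
    count = c(as.integer(counts), as.integer(yes_e)),
    percent = round(100 * c(as.integer(counts), yes_e) / n, 1),
    row.names = NULL)
}

#' Prey-length summaries
#'
#' Mean, sample (n-1) SD, minimum and maximum of measured prey lengths,
#' overall and split into earthworms versus other prey. Items without a
#' measured length are excluded and counted.
#'
#' @param vd A `visit_data` object.
#' @return Data frame with one row per group (`all`, `earthworm`, `other`)
#'   and columns `n`, `mean_cm`, `sd_cm`, `min_cm`, `max_cm`; attribute
#'   `n_unmeasured`. The SD of a single measurement is `NA`.
#' @export
length_summary <- function(vd) {
  stopifnot(inherits(vd, "visit_data"))
  items <- vd$items
  measured <- items[!is.na(items$length_cm), ]
  groups <- list(all = measured,
                 earthworm = measured[measured$is_earthworm == 1L, ],
                 other = measured[measured$is_earthworm == 0L, ])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]$length_cm
    data.frame(group = g, n = length(x),
               mean_cm = if (length(x)) mean(x) else NA_real_,
               sd_cm = if (length(x) > 1) stats::sd(x) else NA_real_,
               min_cm = if (length(x)) min(x) else NA_real_,
               max_cm = if (length(x)) max(x) else NA_real_)
  }))
  attr(out, "n_unmeasured") <- sum(is.na(items$length_cm))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the probability-ordering rule: the sum
#' of hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))  # 34/70
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(is.na(tab)) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("need a 2x2 table of non-negative integer counts")
  }
  if (sum(tab) == 0) stop("all-zero table has no defined test")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via X = -2 * sum(log(p)), referred to the
#' upper tail of a chi-square distribution with 2k degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return List with `statistic`, `df`, `p_value` and `k` (number of
#'   combined tests).
#' @export
#' @examples
#' fisher_combined(c(0.05, 0.05))
fisher_combined <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L || any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(p))
  list(statistic = x, df = 2L * length(p),
       p_value = stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE),
       k = length(p))
}

#' Nestling-age contingency analysis
#'
#' For each nest, builds a young-versus-old 2x2 table of either earthworm
#' versus other identified prey items (`mode = "items"`) or earthworm-only
#' versus all other visits (`mode = "visits"`), applies
#' [fisher_exact_2x2()] per nest, and combines the per-nest p-values with
#' [fisher_combined()]. Per-nest p-values are reported so that results
#' driven by a single nest remain inspectable. Nests in which one age class
#' is unobserved are excluded with a warning and the degrees of freedom
#' adjusted.
#'
#' @param vd A `visit_data` object.
#' @param mode `"items"` or `"visits"`.
#' @return Object of class `contingency_result`: list with `tables`
#'   (per-nest 2x2 matrices), `per_nest_p`, `combined` (the
#'   [fisher_combined()] list) and `mode`.
#' @export
age_contingency <- function(vd, mode = c("items", "visits")) {
  stopifnot(inherits(vd, "visit_data"))
  mode <- match.arg(mode)
  tables <- list()
  for (nest in sort(unique(vd$visits$nest_id))) {
    if (mode == "items") {
      it <- vd$items[vd$items$nest_id == nest & vd$items$taxon != "unknown", ]
      if (nrow(it) == 0L) next
      age <- categorize_age(it$nestling_age_days)
      tab <- table(age, factor(ifelse(it$is_earthworm == 1L, "earthworm",
                                      "other"),
                               levels = c("earthworm", "other")))
    } else {
      v <- vd$visits[vd$visits$nest_id == nest, ]
      tab <- table(v$age_class,
                   factor(ifelse(v$visit_type == "OnlyE", "OnlyE", "other"),
                          levels = c("OnlyE", "other")))
    }
    tab <- as.matrix(tab)
    if (any(rowSums(tab) == 0)) {
      warning("nest ", nest, " lacks one age class; excluded from the ",
              "combined test")
      next
    }
    tables[[nest]] <- tab
  }
  if (length(tables) == 0L) stop("no nest with both age classes represented")
  per_nest_p <- vapply(tables, fisher_exact_2x2, 0)
  structure(list(tables = tables, per_nest_p = per_nest_p,
                 combined = fisher_combined(per_nest_p), mode = mode),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Age-class contingency analysis (", x$mode, " mode), ",
      length(x$per_nest_p), " nests\n", sep = "")
  for (nest in names(x$per_nest_p)) {
    cat(sprintf("  %s: p = %.4g\n", nest, x$per_nest_p[[nest]]))
  }
  cat(sprintf("  combined: X = %.3f on %d df, p = %.4g\n",
              x$combined$statistic, x$combined$df, x$combined$p_value))
  invisible(x)
}
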