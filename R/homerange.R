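# Consumption-to-area model: predicted home-range bands as a function of
# earthworm density and availability, availability-integrated overlap with
# the observed home-range band, and the relative overlap index across
# consumption scenarios.

#' Predicted home-range area for a consumption total
#'
#' Area (m^2) that contains `worms` surfacing earthworms at a given
#' epigeic density and availability fraction:
#' `worms / (density * availability)`.
#'
#' @param worms Positive consumption total (number of earthworms).
#' @param density Positive earthworm density (individuals per m^2).
#' @param availability Fraction in (0, 1\] of the earthworm population
#'   available (detectable and capturable).
#' @return Area in m^2; strictly increasing in `worms`, strictly
#'   decreasing in `density` and `availability`.
#' @export
#' @examples
#' predicted_area(5497, density = 8.7, availability = 0.05) / 1e4  # ~1.26 ha
predicted_area <- function(worms, density, availability) {
  if (any(worms <= 0) || any(density <= 0)) {
    stop("consumption and density must be positive")
  }
  if (any(availability <= 0 | availability > 1)) {
    stop("availability must lie in (0, 1]")
  }
  worms / (density * availability)
}

#' Predicted home-range band across the density range
#'
#' For each availability value, the interval of predicted areas spanned by
#' the low and high epigeic density bounds; the high density gives the
#' lower band edge.
#'
#' @param worms Positive consumption total.
#' @param availability Vector of availability fractions.
#' @param density_low,density_high Epigeic density bounds (0.53 and 8.7
#'   individuals/m^2 by default).
#' @return Matrix with columns `lower` and `upper` (m^2), one row per
#'   availability value.
#' @export
predicted_band <- function(worms, availability, density_low = 0.53,
                           density_high = 8.7) {
  if (density_low <= 0 || density_high <= density_low) {
    stop("need 0 < density_low < density_high")
  }
  cbind(lower = predicted_area(worms, density_high, availability),
        upper = predicted_area(worms, density_low, availability))
}

#' Availability-integrated overlap of predicted and observed home ranges
#'
#' Integrates, over the availability domain, the length (m^2, linear area
#' scale) of the intersection between the predicted band and the observed
#' home-range band, by a left-endpoint Riemann sum at the stated
#' resolution. Units are m^2 x availability fraction.
#'
#' @param worms Positive consumption total.
#' @param observed_band Observed home-range interval in m^2 (default
#'   10-30 ha).
#' @param density_low,density_high Epigeic density bounds (ind/m^2).
#' @param availability_domain Availability interval (default 0.5-5%).
#' @param step Integration step on the availability axis (default 1e-5,
#'   i.e. 0.001 percentage points).
#' @return Non-negative overlap integral.
#' @export
#' @examples
#' overlap_integral(5497, observed_band = c(1e5, 2e5))
overlap_integral <- function(worms, observed_band = c(1e5, 3e5),
                             density_low = 0.53, density_high = 8.7,
                             availability_domain = c(0.005, 0.05),
                             step = 1e-5) {
  stopifnot(length(observed_band) == 2L, observed_band[1] < observed_band[2],
            length(availability_domain) == 2L,
            availability_domain[1] < availability_domain[2], step > 0)
  a <- seq(availability_domain[1], availability_domain[2] - step, by = step)
  band <- predicted_band(worms, a, density_low, density_high)
  lo <- pmax(observed_band[1], band[, "lower"])
  hi <- pmin(observed_band[2], band[, "upper"])
  sum(pmax(0, hi - lo)) * step
}

#' Relative overlap index
#'
#' Each scenario's overlap integral as a percentage of the maximum overlap
#' across the compared scenario set; the maximizing scenario scores exactly
#' 100. If every overlap is zero all indices are defined as 0 with a
#' warning.
#'
#' @param overlaps Numeric vector of non-negative overlap integrals
#'   (optionally named by scenario).
#' @return Vector of indices in \[0, 100\].
#' @export
relative_overlap_index <- function(overlaps) {
  if (length(overlaps) == 0L || any(is.na(overlaps)) || any(overlaps < 0)) {
    stop("overlaps must be non-negative")
  }
  m <- max(overlaps)
  if (m == 0) {
    warning("all overlaps are zero; indices defined as 0")
    return(overlaps * 0)
  }
  100 * overlaps / m
}

#' Scenario grid of overlaps and relative overlap indices
#'
#' Evaluates the comparison set used for the predicted-versus-observed
#' home-range assessment: the brood-only scenario plus family scenarios
#' over a grid of earthworm diet proportions, for each observed-band
#' option. The relative overlap index is normalised within each band
#' option.
#'
#' @param params An [energetics_params()] object.
#' @param p_grid Diet proportions of the family scenarios.
#' @param brood_worms Standardized brood consumption in worms.
#' @param observed_bands Named list of observed home-range intervals in
#'   m^2.
#' @param density_low,density_high,availability_domain,step Passed to
#'   [overlap_integral()].
#' @return Data frame with columns `band`, `scenario`, `p`, `worms`,
#'   `overlap`, `index`.
#' @export
#' @examples
#' g <- scenario_grid()
#' subset(g, band == "10-20 ha" & p %in% c(0.6, 0.7))
scenario_grid <- function(params = energetics_params(),
                          p_grid = seq(0.3, 0.7, by = 0.1),
                          brood_worms = params$printed_brood_consumption_5,
                          observed_bands = list(
                            "10-30 ha" = c(1e5, 3e5),
                            "10-20 ha" = c(1e5, 2e5),
                            "5-20 ha" = c(5e4, 2e5)),
                          density_low = 0.53, density_high = 8.7,
                          availability_domain = c(0.005, 0.05),
                          step = 1e-5) {
  worms <- c(brood_worms, family_consumption(p_grid, params, brood_worms))
  scen <- data.frame(
    scenario = c("brood", sprintf("family p=%.1f", p_grid)),
    p = c(NA, p_grid), worms = worms)
  out <- do.call(rbind, lapply(names(observed_bands), function(bn) {
    ov <- vapply(scen$worms, overlap_integral, 0,
                 observed_band = observed_bands[[bn]],
                 density_low = density_low, density_high = density_high,
                 availability_domain = availability_domain, step = step)
    data.frame(band = bn, scen, overlap = ov,
               index = relative_overlap_index(ov))
  }))
  rownames(out) <- NULL
  out
}
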