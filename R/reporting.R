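#' Aggregate emissions to administrative units
#'
#' Sums the per-pixel net period totals of a bookkeeping run to departments
#' or municipalities and reports average annual emissions plus each unit's
#' share of the national total. Unit totals sum exactly to the national
#' total by construction.
#'
#' @param book A \code{\link{run_grid}} result.
#' @param level \code{"department"} or \code{"municipality"}.
#' @param period Optional period filter (\code{"1990-2000"} or
#'   \code{"2000-2010"}); default both.
#' @return Data frame: unit, period, net tCO2, annual tCO2/yr, share (\%).
#' @export
aggregate_emissions <- function(book, level = c("department", "municipality"),
                                period = NULL) {
  level <- match.arg(level)
  px <- book$pixels
  bad <- is.na(px[[level]]) | px[[level]] == ""
  if (any(bad))
    stop("pixels not mapped to any ", level, ": ",
         paste(utils::head(unique(px$pixel_id[bad]), 10), collapse = ", "))
  if (!is.null(period)) px <- px[px$period %in% period, , drop = FALSE]
  agg <- stats::aggregate(px$net_tco2,
                          by = list(period = px$period, unit = px[[level]]),
                          FUN = sum)
  names(agg) <- c("period", level, "net_tco2")
  nat <- stats::aggregate(net_tco2 ~ period, data = px, FUN = sum)
  agg$annual_tco2_yr <- agg$net_tco2 / 10
  agg$share_pct <- 100 * agg$net_tco2 /
    nat$net_tco2[match(agg$period, nat$period)]
  agg[order(agg$period, -agg$net_tco2), c(level, "period", "net_tco2",
                                          "annual_tco2_yr", "share_pct")]
}

#' Per-capita emissions
#'
#' @param annual_tco2 Average annual emissions, tCO2/yr.
#' @param population Mid-period population (must be positive).
#' @return tCO2 per person per year.
#' @export
per_capita <- function(annual_tco2, population) {
  if (any(population <= 0))
    stop("population must be positive for per-capita emissions")
  annual_tco2 / population
}

#' Emissions per unit of GDP
#'
#' GDP is in thousands of constant-value currency units; emissions in
#' tonnes. The tonne-per-thousand ratio equals kilograms per unit, so the
#' result is kg CO2 per currency unit.
#'
#' @param annual_tco2 Average annual emissions, tCO2/yr.
#' @param gdp_thousand Mid-period GDP in thousands of constant currency
#'   units (must be positive).
#' @return kg CO2 per currency unit.
#' @export
per_gdp <- function(annual_tco2, gdp_thousand) {
  if (any(gdp_thousand <= 0))
    stop("GDP must be positive for per-GDP emissions")
  annual_tco2 / gdp_thousand
}

#' Classify pixels by net flux density
#'
#' Pixels within \eqn{\pm}10 tCO2/km2/yr are neutral (band inclusive);
#' above it, emitting; below, absorbing.
#'
#' @param flux_per_km2 Net flux density per pixel, tCO2/km2/yr.
#' @param band Half-width of the neutral band (default 10).
#' @return List: \code{class} (factor per pixel) and \code{frequencies}
#'   (named proportions summing to 1).
#' @export
classify_pixels <- function(flux_per_km2, band = 10) {
  if (any(!is.finite(flux_per_km2)))
    stop("flux values must be finite")
  cls <- factor(ifelse(flux_per_km2 > band, "emitting",
                       ifelse(flux_per_km2 < -band, "absorbing", "neutral")),
                levels = c("emitting", "neutral", "absorbing"))
  list(class = cls, frequencies = prop.table(table(cls)))
}

#' Count municipalities that are significant net carbon absorbers
#'
#' A municipality is a significant sink when it absorbs at least 1 tCO2 per
#' person per year (threshold inclusive).
#'
#' @param per_capita_by_municipality Numeric vector of per-capita annual
#'   emissions by municipality (negative = absorption).
#' @param threshold Absorption threshold, tCO2/person/yr.
#' @return Integer count.
#' @export
municipal_sinks <- function(per_capita_by_municipality, threshold = 1) {
  sum(per_capita_by_municipality <= -threshold)
}

#' National summary in the shape of the headline results table
#'
#' Combines a bookkeeping run with national population and GDP into total
#' and annual emissions, per-capita and per-GDP indicators per period.
#'
#' @param book A \code{\link{run_grid}} result.
#' @param admin Admin-statistics table with \code{level == "national"} rows
#'   carrying \code{period}, \code{population}, \code{gdp_thousand_bs}.
#' @return Data frame with one row per period.
#' @export
national_summary <- function(book, admin) {
  nat <- admin[admin$level == "national", ]
  tt <- book$totals
  i <- match(tt$period, nat$period)
  if (anyNA(i)) stop("admin table lacks national rows for some periods")
  data.frame(period = tt$period,
             total_tco2 = tt$net_tco2,
             annual_tco2_yr = tt$annual_tco2_yr,
             population = nat$population[i],
             per_capita = per_capita(tt$annual_tco2_yr, nat$population[i]),
             gdp_thousand_bs = nat$gdp_thousand_bs[i],
             per_gdp_kg_bs = per_gdp(tt$annual_tco2_yr,
                                     nat$gdp_thousand_bs[i]))
}
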