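#' Define a sensitivity scenario
#'
#' A scenario is a named set of deviations from the baseline assumptions:
#' the biomass percentile used for mature carbon ("clearing less dense
#' forest first" uses the 25th), the share of cleared land managed as
#' pasture with intact soil carbon, the fraction of soil carbon lost under
#' agriculture, the equivalent regrowth age of degraded forest, and the two
#' static-land adjustments (soil-erosion emissions and the mature-forest
#' sink).
#'
#' @param name Scenario label; \code{"baseline"} must keep every default.
#' @param cap_percentile Biomass percentile for mature carbon (50 baseline).
#' @param pasture_share Share of each clearing event's area converted to
#'   pasture, where soil carbon stays intact (0 baseline, 0.20 variant).
#' @param soc_loss_frac Fraction of soil carbon lost over the loss horizon
#'   (0.25 baseline, 0.35 "more aggressive agriculture").
#' @param degraded_equiv_age Regrowth age assigned to degraded forest
#'   (25 baseline, 15 "severely degraded").
#' @param erosion List: \code{enabled},
#'   \code{eroding_share_of_nonforest} (0.80), \code{annual_soc_loss}
#'   (0.01), \code{oxidized_frac} (0.015), \code{mode}
#'   (\code{"depleting"} or \code{"constant"} soil stock).
#' @param mature_sink List: \code{enabled}, \code{growth_per_decade} (0.04).
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name = "baseline",
                          cap_percentile = 50,
                          pasture_share = 0,
                          soc_loss_frac = 0.25,
                          degraded_equiv_age = 25,
                          erosion = list(enabled = FALSE,
                                         eroding_share_of_nonforest = 0.80,
                                         annual_soc_loss = 0.01,
                                         oxidized_frac = 0.015,
                                         mode = "depleting"),
                          mature_sink = list(enabled = FALSE,
                                             growth_per_decade = 0.04)) {
  for (v in c(pasture_share, soc_loss_frac,
              erosion$eroding_share_of_nonforest, erosion$annual_soc_loss,
              erosion$oxidized_frac, mature_sink$growth_per_decade))
    if (!is.null(v) && (v < 0 || v > 1))
      stop("scenario shares and fractions must lie in [0, 1]")
  if (cap_percentile <= 0 || cap_percentile >= 100)
    stop("cap_percentile must lie strictly between 0 and 100")
  if (degraded_equiv_age <= 0)
    stop("degraded_equiv_age must be positive")
  spec <- structure(list(name = name, cap_percentile = cap_percentile,
                         pasture_share = pasture_share,
                         soc_loss_frac = soc_loss_frac,
                         degraded_equiv_age = degraded_equiv_age,
                         erosion = utils::modifyList(
                           list(enabled = FALSE,
                                eroding_share_of_nonforest = 0.80,
                                annual_soc_loss = 0.01,
                                oxidized_frac = 0.015, mode = "depleting"),
                           erosion),
                         mature_sink = utils::modifyList(
                           list(enabled = FALSE, growth_per_decade = 0.04),
                           mature_sink)),
                    class = "scenario_spec")
  if (name == "baseline") {
    base <- c(cap_percentile = 50, pasture_share = 0, soc_loss_frac = 0.25,
              degraded_equiv_age = 25)
    got <- unlist(spec[names(base)])
    if (any(got != base) || isTRUE(spec$erosion$enabled) ||
        isTRUE(spec$mature_sink$enabled))
      stop("a scenario named 'baseline' must keep all baseline values")
  }
  spec
}

#' The standard scenario set
#'
#' Returns the baseline plus the published sensitivity variants: the four
#' land-use-change deviations (25th biomass percentile, 20\% pasture, 35\%
#' soil-carbon loss, 15-year degraded forest), the two static-land
#' adjustments (soil erosion, mature-forest sink), and a combined
#' static-land run.
#'
#' @return Named list of \code{\link{scenario_spec}} objects (8 entries).
#' @export
preset_scenarios <- function() {
  list(
    baseline = scenario_spec("baseline"),
    clearing_less_dense_first = scenario_spec("clearing_less_dense_first",
                                              cap_percentile = 25),
    pasture_20 = scenario_spec("pasture_20", pasture_share = 0.20),
    aggressive_agriculture = scenario_spec("aggressive_agriculture",
                                           soc_loss_frac = 0.35),
    severely_degraded = scenario_spec("severely_degraded",
                                      degraded_equiv_age = 15),
    erosion = scenario_spec("erosion", erosion = list(enabled = TRUE)),
    mature_sink = scenario_spec("mature_sink",
                                mature_sink = list(enabled = TRUE)),
    static_land_combined = scenario_spec("static_land_combined",
                                         erosion = list(enabled = TRUE),
                                         mature_sink = list(enabled = TRUE))
  )
}

#' Apply a scenario to a base configuration
#'
#' Pure function: returns a copy of the base configuration list in which
#' only the knobs named by the scenario differ.
#'
#' @param base_config Configuration list (as used by
#'   \code{\link{build_params}} and the engine).
#' @param spec A \code{\link{scenario_spec}}.
#' @return The adjusted configuration list.
#' @export
apply_scenario <- function(base_config, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- base_config
  cfg$percentile <- spec$cap_percentile
  cfg$soc_loss_frac <- spec$soc_loss_frac
  cfg$degraded_equiv_age <- spec$degraded_equiv_age
  cfg$pasture_share <- spec$pasture_share
  cfg$erosion <- spec$erosion
  cfg$mature_sink <- spec$mature_sink
  cfg
}

# Rebuild/adjust a forest_params object under a scenario: constants
# (soc_loss_frac), degraded age, and CAP percentile (re-estimated from the
# stored biomass table when the percentile changes).
apply_scenario_params <- function(params, spec) {
  if (is.null(spec)) return(params)
  cst <- params$constants
  cst$soc_loss_frac <- spec$soc_loss_frac
  if (spec$cap_percentile != params$percentile) {
    if (is.null(params$biomass_table))
      stop("scenario changes the biomass percentile but the parameter set ",
           "carries no biomass samples to re-estimate mature carbon from")
    cfg <- params$config
    cfg$percentile <- spec$cap_percentile
    cfg$degraded_equiv_age <- spec$degraded_equiv_age
    return(build_params(params$biomass_table, cfg, cst))
  }
  params$constants <- cst
  params$types$degraded_equiv_age <- spec$degraded_equiv_age
  params
}

apply_scenario_config <- function(config, spec) {
  if (is.null(spec)) return(config)
  config$pasture_share <- spec$pasture_share
  config
}

# Cover columns bounding a named period.
period_covers <- function(period) {
  switch(period,
         "1990-2000" = c("cover_1990", "cover_2000"),
         "2000-2010" = c("cover_2000", "cover_2010"),
         stop("unknown period '", period, "'"))
}

#' Soil-erosion CO2 flux from static non-forested land
#'
#' For the eroding share of land that is non-forested throughout a period,
#' a fixed fraction of the soil organic carbon stock erodes each year and a
#' small fraction of the eroded carbon is oxidised to CO2 (the remainder is
#' assumed redeposited and reintegrated into soils downslope). In the
#' default depleting mode the soil stock shrinks by the eroded amount each
#' year; the constant mode keeps the stock fixed.
#'
#' @param grid Pixel grid table.
#' @param params A \code{\link{build_params}} object.
#' @param spec A \code{\link{scenario_spec}} with \code{erosion$enabled}.
#' @param period \code{"1990-2000"} or \code{"2000-2010"}.
#' @return List: \code{annual} (length-10 tCO2/yr series), \code{total},
#'   \code{pixel_total} (per-pixel period totals, tCO2).
#' @export
erosion_flux <- function(grid, params, spec, period = "2000-2010") {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!isTRUE(spec$erosion$enabled))
    stop("erosion is not enabled in this scenario")
  er <- spec$erosion
  cc <- period_covers(period)
  nonforest <- !(grid[[cc[1]]] %in% c("forest", "regrowth")) &
    !(grid[[cc[2]]] %in% c("forest", "regrowth"))
  area_er <- ifelse(nonforest, grid$area_ha * er$eroding_share_of_nonforest, 0)
  stock <- grid$soc_ref * area_er  # tC
  co2 <- params$constants$co2_per_c
  annual <- numeric(10)
  pixel_total <- numeric(nrow(grid))
  for (t in 1:10) {
    eroded <- er$annual_soc_loss * stock
    emit <- er$oxidized_frac * eroded * co2
    annual[t] <- sum(emit)
    pixel_total <- pixel_total + emit
    if (identical(er$mode, "depleting")) stock <- stock - eroded
  }
  list(annual = annual, total = sum(annual), pixel_total = pixel_total)
}

#' Mature-forest sink flux
#'
#' Mature, undisturbed forests accumulating biomass act as a carbon sink:
#' aboveground carbon (and root carbon with it) grows by a fixed fraction
#' of CAP per decade, spread linearly over the years. Applied to pixels
#' observed as forest at both ends of a period; the flux is negative
#' (absorption).
#'
#' @param grid Pixel grid table.
#' @param params A \code{\link{build_params}} object.
#' @param spec A \code{\link{scenario_spec}} with \code{mature_sink$enabled}.
#' @param period \code{"1990-2000"} or \code{"2000-2010"}.
#' @return List: \code{annual} (length-10 tCO2/yr series, negative),
#'   \code{total}, \code{pixel_total}.
#' @export
mature_sink_flux <- function(grid, params, spec, period = "2000-2010") {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!isTRUE(spec$mature_sink$enabled))
    stop("the mature-forest sink is not enabled in this scenario")
  gpd <- spec$mature_sink$growth_per_decade
  cc <- period_covers(period)
  mature <- grid[[cc[1]]] == "forest" & grid[[cc[2]]] == "forest" &
    !is.na(grid$forest_type)
  pixel_total <- numeric(nrow(grid))
  if (any(mature)) {
    i <- which(mature)
    t_idx <- match(as.character(grid$forest_type[i]), params$types$name)
    cap <- params$types$cap_agc[t_idx]
    rs <- params$types$root_shoot[t_idx]
    pixel_total[i] <- -gpd * cap * (1 + rs) * grid$area_ha[i] *
      params$constants$co2_per_c
  }
  list(annual = rep(sum(pixel_total) / 10, 10), total = sum(pixel_total),
       pixel_total = pixel_total)
}

#' Tier 1 committed-emissions estimate
#'
#' The naive national inventory calculation: average annual mature-forest
#' loss times the national average aboveground carbon density, converted to
#' CO2. Ignores regrowth, degradation, root and soil carbon, and the timing
#' of decomposition.
#'
#' @param forest_area_start,forest_area_end Mature forest area at the
#'   period's endpoints, ha (degraded and regenerating forest excluded).
#' @param mean_agc Average aboveground carbon density, tC/ha.
#' @param years Period length in years.
#' @return Average annual emissions, tCO2/yr (negative if forest expanded).
#' @export
#' @examples
#' tier1(55.0e6, 52.6e6, 114, 10)
tier1 <- function(forest_area_start, forest_area_end, mean_agc, years = 10) {
  stopifnot(years > 0)
  ((forest_area_start - forest_area_end) / years) * mean_agc * (44 / 12)
}

#' Run the full scenario set over a grid
#'
#' Runs the bookkeeping engine once per scenario and tabulates average
#' annual net emissions (and per-capita values when national population is
#' supplied) for each period — the shape of the published sensitivity
#' tables.
#'
#' @param grid Pixel grid table.
#' @param params Baseline \code{\link{build_params}} object (must carry the
#'   biomass sample table if any scenario changes the percentile).
#' @param scenarios Named list of \code{\link{scenario_spec}}s; defaults to
#'   \code{\link{preset_scenarios}()}.
#' @param admin Optional admin-statistics table (see
#'   \code{\link{gen_landscape}}) for per-capita columns.
#' @param config Engine options.
#' @return Data frame: one row per scenario with annual tCO2/yr per period
#'   (and per-capita columns when \code{admin} is given).
#' @export
run_scenarios <- function(grid, params, scenarios = preset_scenarios(),
                          admin = NULL, config = list()) {
  rows <- lapply(scenarios, function(sc) {
    bk <- run_grid(grid, params, scenario = sc, config = config)
    data.frame(scenario = sc$name,
               annual_tco2_1990_2000 = bk$totals$annual_tco2_yr[1],
               annual_tco2_2000_2010 = bk$totals$annual_tco2_yr[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(admin)) {
    nat <- admin[admin$level == "national", ]
    p1 <- nat$population[nat$period == "1990-2000"]
    p2 <- nat$population[nat$period == "2000-2010"]
    out$per_capita_1990_2000 <- per_capita(out$annual_tco2_1990_2000, p1)
    out$per_capita_2000_2010 <- per_capita(out$annual_tco2_2000_2010, p2)
  }
  out
}
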