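# Cohort engine internals
#
# Cohorts are rows of a numeric matrix: a sub-pixel area fraction sharing a
# land class, regrowth age and soil state. Classes are coded:
#   1 forest (mature), 2 regrowth, 3 degraded, 4 agriculture,
#   5 other_vegetation, 6 nonvegetated
# Column layout: cls, frac, age, agc, soc, years_ag, ever_cleared, soc_frozen
# `soc_frozen` marks cleared land managed as pasture (soil carbon intact).

.COVER_CLASSES <- c("forest", "regrowth", "agriculture",
                    "other_vegetation", "nonvegetated")
.CLS <- c(forest = 1, regrowth = 2, degraded = 3, agriculture = 4,
          other_vegetation = 5, nonvegetated = 6)
.COHORT_COLS <- c("cls", "frac", "age", "agc", "soc", "years_ag",
                  "ever_cleared", "soc_frozen")

new_cohorts <- function(cls, frac, age, agc, soc, years_ag = 0,
                        ever_cleared = 0, soc_frozen = 0) {
  m <- cbind(cls = cls, frac = frac, age = age, agc = agc, soc = soc,
             years_ag = years_ag, ever_cleared = ever_cleared,
             soc_frozen = soc_frozen)
  colnames(m) <- .COHORT_COLS
  m
}

# Internal cohort classes matching an observed cover class (source groups).
source_group <- function(cover) {
  switch(cover,
         forest = c(1, 2, 3),
         regrowth = c(2, 3),
         agriculture = 4,
         other_vegetation = 5,
         nonvegetated = 6,
         stop("unknown land-cover class '", cover, "'"))
}

#' Initialise the 1990 cohort state of a pixel
#'
#' Seeds the cohort set from the first observed land-cover class. Mature
#' forest starts at CAP with undisturbed soil; regrowth is split into equal
#' cohorts over a configurable initial age range (default ages 1--10) with
#' soil partially recovered from an assumed prior agricultural spell;
#' agricultural land starts at 5 tC/ha with soil depleted according to the
#' assumed prior duration (default 10 years).
#'
#' @param pixel One-row data frame (or list) with at least \code{forest_type},
#'   \code{soc_ref} and \code{cover_1990}; \code{agb_biomass_t_ha} is used
#'   when \code{use_observed_agc} is set.
#' @param params A \code{\link{build_params}} object.
#' @param config List of options: \code{init_regrowth_ages} (integer vector,
#'   default \code{1:10}), \code{prior_ag_years} (default 10),
#'   \code{use_observed_agc} (default FALSE: mature forest starts at the
#'   type CAP rather than the pixel's map biomass).
#' @return A cohort matrix (internal representation).
#' @export
init_state <- function(pixel, params, config = list()) {
  cover <- as.character(pixel$cover_1990)
  if (!cover %in% .COVER_CLASSES)
    stop("unknown land-cover class '", cover, "'")
  cst <- params$constants
  needs_type <- cover %in% c("forest", "regrowth")
  if (needs_type && (is.null(pixel$forest_type) || is.na(pixel$forest_type)))
    stop("pixel ", pixel$pixel_id %||% "?",
         ": forest_type required for cover class '", cover, "'")
  p <- if (!is.null(pixel$forest_type) && !is.na(pixel$forest_type))
    params_row(params, as.character(pixel$forest_type)) else NULL
  soc_ref <- pixel$soc_ref

  if (cover == "forest") {
    agc <- p$cap_agc
    if (isTRUE(config$use_observed_agc) && !is.null(pixel$agb_biomass_t_ha) &&
        !is.na(pixel$agb_biomass_t_ha))
      agc <- min(cst$carbon_fraction * pixel$agb_biomass_t_ha, p$cap_agc)
    return(new_cohorts(1, 1, 0, agc, soc_ref))
  }
  if (cover == "regrowth") {
    ages <- config$init_regrowth_ages %||% 1:10
    prior <- config$prior_ag_years %||% 10
    slope <- cst$soc_loss_frac * soc_ref / cst$soc_loss_horizon
    soc0 <- soc_ref - slope * min(prior, cst$soc_loss_horizon)
    soc <- pmin(soc0 + cst$recovery_slope_factor * slope * ages, soc_ref)
    return(new_cohorts(2, rep(1 / length(ages), length(ages)), ages,
                       agb_regrowth(ages, p), soc,
                       years_ag = min(prior, cst$soc_loss_horizon),
                       ever_cleared = 1))
  }
  if (cover == "agriculture") {
    # Land already agricultural at the first epoch was cleared before the
    # ledger opens: its soil reflects the assumed prior spell but emits
    # nothing further while it stays in use (the central estimate books no
    # emissions from land with no observed use change). Abandonment later
    # still recovers the accumulated deficit.
    prior <- min(config$prior_ag_years %||% 10, cst$soc_loss_horizon)
    slope <- cst$soc_loss_frac * soc_ref / cst$soc_loss_horizon
    return(new_cohorts(4, 1, 0, cst$agri_agc, soc_ref - slope * prior,
                       years_ag = cst$soc_loss_horizon, ever_cleared = 1))
  }
  if (cover == "other_vegetation")
    return(new_cohorts(5, 1, 0, cst$other_veg_agc, soc_ref))
  new_cohorts(6, 1, 0, 0, soc_ref)  # nonvegetated
}

#' Expand an observed decadal transition into annual conversion events
#'
#' The decadal maps say which class a pixel was in at each epoch, not when
#' within the decade it changed. The default rule spreads the conversion
#' uniformly: one tenth of the transitioning area converts in each year.
#' Degradation (forest observed as regrowth on never-cleared land) and
#' recovery release (degraded observed as forest) are single
#' reclassification events in year one. Identity transitions produce no
#' events; cohorts keep aging and recovering regardless.
#'
#' @param cover_start,cover_end Observed classes at the decade's endpoints.
#' @param decade_years Years in the observation interval (default 10).
#' @param cohort_rule \code{"uniform"} (1/10 of the area each year) or
#'   \code{"midpoint"} (all area converts mid-decade).
#' @return Data frame with columns \code{year} and \code{frac_of_source}
#'   (fraction of the source area present at decade start), with the target
#'   class attached as attribute \code{"to"}. Zero rows for identity pairs.
#' @export
expand_transition <- function(cover_start, cover_end, decade_years = 10,
                              cohort_rule = c("uniform", "midpoint")) {
  cohort_rule <- match.arg(cohort_rule)
  for (cl in c(cover_start, cover_end))
    if (!cl %in% .COVER_CLASSES)
      stop("unknown land-cover class '", cl, "' (valid: ",
           paste(.COVER_CLASSES, collapse = ", "), ")")
  if (cover_start == cover_end ||
      (cover_start == "regrowth" && cover_end == "forest")) {
    # identity, or regrowth maturing into forest: aging only, no events;
    # degraded cohorts released to recover are handled below
    if (cover_start == "regrowth" && cover_end == "forest")
      return(structure(data.frame(year = 1, frac_of_source = 1),
                       to = cover_end, single = TRUE,
                       class = c("transition_schedule", "data.frame")))
    return(structure(data.frame(year = integer(0),
                                frac_of_source = numeric(0)),
                     to = cover_end,
                     class = c("transition_schedule", "data.frame")))
  }
  if (cover_start == "forest" && cover_end == "regrowth") {
    # degradation of never-cleared forest is one reclassification event;
    # previously cleared cohorts under the same observation keep growing
    return(structure(data.frame(year = 1, frac_of_source = 1),
                     to = cover_end, single = TRUE,
                     class = c("transition_schedule", "data.frame")))
  }
  sched <- if (cohort_rule == "uniform")
    data.frame(year = seq_len(decade_years),
               frac_of_source = rep(1 / decade_years, decade_years))
  else
    data.frame(year = ceiling(decade_years / 2), frac_of_source = 1)
  structure(sched, to = cover_end,
            class = c("transition_schedule", "data.frame"))
}

# Vectorised one-year soil dynamics over cohort rows (same rules as
# soc_step, applied by class).
step_soil <- function(co, soc_ref, cst) {
  slope <- cst$soc_loss_frac * soc_ref / cst$soc_loss_horizon
  floor_soc <- (1 - cst$soc_loss_frac) * soc_ref
  agri <- co[, "cls"] == 4 & co[, "soc_frozen"] == 0 &
    co[, "years_ag"] < cst$soc_loss_horizon
  if (any(agri)) {
    co[agri, "soc"] <- pmax(co[agri, "soc"] - slope, floor_soc)
    co[agri, "years_ag"] <- co[agri, "years_ag"] + 1
  }
  recov <- co[, "cls"] %in% c(1, 2, 3, 5) & co[, "soc"] < soc_ref
  if (any(recov))
    co[recov, "soc"] <- pmin(co[recov, "soc"] +
                               cst$recovery_slope_factor * slope, soc_ref)
  co
}

#' Advance a pixel's cohort set by one year
#'
#' Dynamics run first: regrowth cohorts age one year along the logistic
#' curve, degraded cohorts hold their equivalent age, agricultural soil
#' decomposes and recovering soil climbs back. Conversion events scheduled
#' for this year then apply at year end: clearing drops aboveground carbon
#' to the agricultural level instantly, abandonment starts a regrowth cohort
#' at age zero, degradation reclassifies never-cleared forest at the
#' degraded equivalent age.
#'
#' @param cohorts Cohort matrix.
#' @param events List of this year's conversion events, each a list with
#'   \code{from} (observed source class), \code{to}, and \code{area_frac}
#'   (absolute fraction of the pixel to convert).
#' @param p One forest type's parameters (may be NULL for never-forested
#'   pixels).
#' @param constants A \code{\link{global_constants}} object.
#' @param soc_ref Reference SOC of the pixel, tC/ha.
#' @param pasture_share Fraction of newly cleared area managed as pasture
#'   (soil carbon intact).
#' @return The cohort matrix after one year.
#' @export
step_year <- function(cohorts, events = list(), p, constants, soc_ref,
                      pasture_share = 0) {
  co <- cohorts
  if (abs(sum(co[, "frac"]) - 1) > 1e-9)
    stop("cohort area fractions do not sum to 1")
  # aging along the regrowth curve
  gr <- co[, "cls"] == 2
  if (any(gr)) {
    co[gr, "age"] <- co[gr, "age"] + 1
    co[gr, "agc"] <- agb_regrowth(co[gr, "age"], p)
  }
  co <- step_soil(co, soc_ref, constants)

  for (ev in events) {
    src <- source_group(ev$from)
    in_src <- co[, "cls"] %in% src & co[, "frac"] > 1e-12
    avail <- sum(co[in_src, "frac"])
    take <- min(ev$area_frac, avail)
    if (take <= 1e-12) next
    prop <- take / avail
    idx <- which(in_src)
    moved <- co[idx, , drop = FALSE]
    moved[, "frac"] <- moved[, "frac"] * prop
    co[idx, "frac"] <- co[idx, "frac"] * (1 - prop)
    co <- rbind(co, convert_cohorts(moved, ev$to, p, constants,
                                    pasture_share))
  }
  co <- co[co[, "frac"] > 1e-12, , drop = FALSE]
  if (abs(sum(co[, "frac"]) - 1) > 1e-9)
    stop("cohort area fractions do not sum to 1 after conversions")
  merge_cohorts(co)
}

# Apply one conversion to a set of moved cohort rows.
convert_cohorts <- function(moved, to, p, cst, pasture_share = 0) {
  out <- NULL
  for (i in seq_len(nrow(moved))) {
    row <- moved[i, , drop = FALSE]
    cls <- row[, "cls"]
    conv <- switch(to,
      agriculture = {
        row[, c("cls", "age")] <- c(4, 0)
        row[, "agc"] <- cst$agri_agc
        row[, "ever_cleared"] <- 1
        if (pasture_share > 0) {
          past <- row
          past[, "frac"] <- row[, "frac"] * pasture_share
          past[, "soc_frozen"] <- 1
          row[, "frac"] <- row[, "frac"] * (1 - pasture_share)
          rbind(row, past)
        } else row
      },
      regrowth = {
        if (cls == 1 && row[, "ever_cleared"] == 0) {
          # degradation: never-cleared forest partially loses carbon
          row[, "cls"] <- 3
          row[, "age"] <- p$degraded_equiv_age
          row[, "agc"] <- degraded_agc(p)
        } else if (cls %in% c(4, 5, 6)) {
          # abandonment: regrowth from the current (low) carbon level
          row[, "cls"] <- 2
          row[, "age"] <- equivalent_age(row[, "agc"], p)
          row[, "agc"] <- agb_regrowth(row[, "age"], p)
          row[, "soc_frozen"] <- 0
        }
        # cls 2 or 3 observed as regrowth: unchanged (degraded holds age)
        row
      },
      forest = {
        if (cls == 3) {
          row[, "cls"] <- 2  # degraded released: recovers along the curve
        } else if (cls %in% c(4, 5, 6)) {
          row[, "cls"] <- 2
          row[, "age"] <- equivalent_age(row[, "agc"], p)
          row[, "agc"] <- agb_regrowth(row[, "age"], p)
          row[, "soc_frozen"] <- 0
        }
        row
      },
      other_vegetation = {
        row[, c("cls", "age")] <- c(5, 0)
        row[, "agc"] <- cst$other_veg_agc
        row[, "soc_frozen"] <- 0
        row
      },
      nonvegetated = {
        row[, c("cls", "age")] <- c(6, 0)
        row[, "agc"] <- 0
        row
      },
      stop("unknown land-cover class '", to, "'"))
    out <- rbind(out, conv)
  }
  out
}

# Collapse numerically identical cohorts to keep the state small.
merge_cohorts <- function(co) {
  if (nrow(co) <= 1) return(co)
  key <- apply(round(co[, c("cls", "age", "agc", "soc", "years_ag",
                            "ever_cleared", "soc_frozen"), drop = FALSE], 9),
               1, paste, collapse = "|")
  if (!anyDuplicated(key)) return(co)
  frac <- tapply(co[, "frac"], key, sum)
  first <- !duplicated(key)
  out <- co[first, , drop = FALSE]
  out[, "frac"] <- frac[key[first]]
  out
}

# Total carbon stock of a cohort set, tC (absolute, given pixel area in ha).
cohort_stock <- function(co, area_ha, root_shoot) {
  sum(co[, "frac"] * area_ha * (co[, "agc"] * (1 + root_shoot) + co[, "soc"]))
}

#' Run the bookkeeping engine for one pixel
#'
#' Steps the pixel's cohorts annually through the two observed decades
#' (1990--2000, 2000--2010), carrying state across the epoch boundary, and
#' returns the annual net CO2 flux series and period totals. Positive flux
#' is an emission to the atmosphere. Never-forested pixels (no forest type
#' and no forest/regrowth observation) carry zero land-use-change flux.
#'
#' @param pixel One-row data frame or list (see \code{\link{init_state}};
#'   also needs \code{area_ha} and the three cover columns).
#' @param params A \code{\link{build_params}} object.
#' @param scenario A \code{\link{scenario_spec}} or NULL for baseline.
#' @param config Engine options (see \code{\link{init_state}} and
#'   \code{\link{expand_transition}}); element \code{cohort_rule} selects
#'   the within-decade timing rule.
#' @return List with \code{periods} (character), \code{annual} (2 x 10
#'   matrix of tCO2/yr), \code{period_total} (tCO2), \code{stock_start} and
#'   \code{stock_end} (tC).
#' @export
run_pixel <- function(pixel, params, scenario = NULL, config = list()) {
  if (!is.null(scenario)) {
    params <- apply_scenario_params(params, scenario)
    config <- apply_scenario_config(config, scenario)
  }
  pasture_share <- config$pasture_share %||% 0
  cohort_rule <- config$cohort_rule %||% "uniform"
  cst <- params$constants
  covers <- as.character(c(pixel$cover_1990, pixel$cover_2000,
                           pixel$cover_2010))
  periods <- c("1990-2000", "2000-2010")
  never_forested <- (is.null(pixel$forest_type) || is.na(pixel$forest_type)) &&
    !any(covers %in% c("forest", "regrowth"))
  if (never_forested) {
    ann <- matrix(0, 2, 10, dimnames = list(periods, NULL))
    return(list(periods = periods, annual = ann,
                period_total = c(0, 0), stock_start = c(NA, NA),
                stock_end = c(NA, NA)))
  }
  p <- params_row(params, as.character(pixel$forest_type))
  co <- init_state(pixel, params, config)
  ann <- matrix(0, 2, 10, dimnames = list(periods, NULL))
  ptot <- s0 <- s1 <- numeric(2)
  for (d in 1:2) {
    sched <- expand_transition(covers[d], covers[d + 1],
                               cohort_rule = cohort_rule)
    to <- attr(sched, "to")
    src_frac0 <- sum(co[co[, "cls"] %in% source_group(covers[d]), "frac"])
    s0[d] <- cohort_stock(co, pixel$area_ha, p$root_shoot)
    prev <- s0[d]
    for (t in 1:10) {
      evs <- list()
      rows <- sched[sched$year == t, , drop = FALSE]
      if (nrow(rows))
        evs <- list(list(from = covers[d], to = to,
                         area_frac = rows$frac_of_source * src_frac0))
      co <- step_year(co, evs, p, cst, pixel$soc_ref, pasture_share)
      stk <- cohort_stock(co, pixel$area_ha, p$root_shoot)
      ann[d, t] <- (prev - stk) * cst$co2_per_c
      prev <- stk
    }
    s1[d] <- prev
    ptot[d] <- sum(ann[d, ])
    mb <- (s0[d] - s1[d]) * cst$co2_per_c
    if (abs(ptot[d] - mb) > 1e-6 * max(1, abs(mb)))
      stop("mass balance violated for pixel ", pixel$pixel_id %||% "?",
           " period ", periods[d])
  }
  list(periods = periods, annual = ann, period_total = ptot,
       stock_start = s0, stock_end = s1)
}

#' Run the bookkeeping model over a pixel grid
#'
#' The main entry point of the package: applies the Tier 3 cohort engine to
#' every pixel of a grid, optionally under a sensitivity scenario, adds the
#' static-land fluxes (soil erosion, mature-forest sink) when the scenario
#' enables them, and aggregates to national annual series and period totals.
#'
#' @param grid Data frame of pixel records: \code{pixel_id}, \code{area_ha},
#'   \code{forest_type}, \code{agb_biomass_t_ha}, \code{soc_ref},
#'   \code{department}, \code{municipality}, \code{cover_1990},
#'   \code{cover_2000}, \code{cover_2010}.
#' @param params A \code{\link{build_params}} object.
#' @param scenario A \code{\link{scenario_spec}} or NULL for baseline.
#' @param config Engine options passed to \code{\link{run_pixel}}.
#' @return An object of class \code{bookkeeping}: list with \code{pixels}
#'   (per pixel and period: land-use-change, erosion and mature-sink
#'   components, net total and flux density), \code{annual} (national 2 x 10
#'   tCO2/yr matrix), \code{totals} (per-period national summary),
#'   \code{params}, \code{scenario}.
#' @export
run_grid <- function(grid, params, scenario = NULL, config = list()) {
  validate_grid(grid)
  periods <- c("1990-2000", "2000-2010")
  n <- nrow(grid)
  lucc <- matrix(0, n, 2)
  annual <- matrix(0, 2, 10, dimnames = list(periods, NULL))
  for (i in seq_len(n)) {
    res <- run_pixel(grid[i, ], params, scenario, config)
    lucc[i, ] <- res$period_total
    annual <- annual + res$annual
  }
  eff_params <- if (is.null(scenario)) params
                else apply_scenario_params(params, scenario)
  ero <- matrix(0, n, 2)
  snk <- matrix(0, n, 2)
  if (!is.null(scenario) && isTRUE(scenario$erosion$enabled)) {
    for (d in 1:2) {
      ef <- erosion_flux(grid, eff_params, scenario, period = periods[d])
      ero[, d] <- ef$pixel_total
      annual[d, ] <- annual[d, ] + ef$annual
    }
  }
  if (!is.null(scenario) && isTRUE(scenario$mature_sink$enabled)) {
    for (d in 1:2) {
      sf <- mature_sink_flux(grid, eff_params, scenario, period = periods[d])
      snk[, d] <- sf$pixel_total
      annual[d, ] <- annual[d, ] + sf$annual
    }
  }
  net <- lucc + ero + snk
  pixels <- data.frame(
    pixel_id = rep(grid$pixel_id, 2),
    department = rep(grid$department, 2),
    municipality = rep(grid$municipality, 2),
    area_ha = rep(grid$area_ha, 2),
    period = rep(periods, each = n),
    lucc_tco2 = c(lucc), erosion_tco2 = c(ero), sink_tco2 = c(snk),
    net_tco2 = c(net),
    flux_tco2_km2_yr = c(net) / (rep(grid$area_ha, 2) / 100) / 10,
    stringsAsFactors = FALSE)
  tot <- data.frame(
    period = periods,
    lucc_tco2 = colSums(lucc), erosion_tco2 = colSums(ero),
    sink_tco2 = colSums(snk), net_tco2 = colSums(net),
    annual_tco2_yr = colSums(net) / 10)
  if (max(abs(rowSums(annual) - tot$net_tco2)) >
      1e-6 * max(1, max(abs(tot$net_tco2))))
    stop("aggregation mismatch: annual series do not sum to period totals")
  structure(list(pixels = pixels, annual = annual, totals = tot,
                 params = eff_params, scenario = scenario,
                 n_pixels = n),
            class = "bookkeeping")
}

#' @rdname run_grid
#' @export
bookkeep <- run_grid

#' Validate a pixel grid table
#'
#' Checks column presence, positive areas, the land-cover vocabulary, and
#' that a forest type is defined wherever an epoch observes forest or
#' regrowth.
#'
#' @param grid Pixel grid data frame.
#' @return The grid, invisibly, if valid; otherwise an error.
#' @export
validate_grid <- function(grid) {
  need <- c("pixel_id", "area_ha", "forest_type", "soc_ref", "department",
            "municipality", "cover_1990", "cover_2000", "cover_2010")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("grid is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(grid$area_ha <= 0)) stop("all pixel areas must be positive")
  if (any(grid$soc_ref < 0)) stop("soc_ref must be non-negative")
  for (col in c("cover_1990", "cover_2000", "cover_2010")) {
    bad <- !grid[[col]] %in% .COVER_CLASSES
    if (any(bad))
      stop("invalid land-cover class in ", col, ": ",
           paste(unique(grid[[col]][bad]), collapse = ", "))
    woody <- grid[[col]] %in% c("forest", "regrowth")
    if (any(woody & is.na(grid$forest_type)))
      stop("forest_type missing for pixels observed as forest/regrowth: ",
           paste(utils::head(grid$pixel_id[woody & is.na(grid$forest_type)], 5),
                 collapse = ", "))
  }
  invisible(grid)
}

#' @export
print.bookkeeping <- function(x, ...) {
  cat("Tier 3 carbon bookkeeping run —", x$n_pixels, "pixels",
      if (!is.null(x$scenario)) paste0("(scenario: ", x$scenario$name, ")")
      else "(baseline)", "\n")
  df <- x$totals
  df[-1] <- lapply(df[-1], function(v) formatC(round(v), format = "d",
                                               big.mark = ","))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.bookkeeping <- function(object, admin = NULL, ...) {
  out <- list(totals = object$totals,
              by_department = aggregate_emissions(object, level = "department"))
  if (!is.null(admin)) {
    nat <- admin[admin$level == "national", ]
    pc <- pg <- rep(NA_real_, 2)
    for (d in 1:2) {
      row <- nat[nat$period == object$totals$period[d], ]
      if (nrow(row)) {
        pc[d] <- per_capita(object$totals$annual_tco2_yr[d],
                            row$population)
        pg[d] <- per_gdp(object$totals$annual_tco2_yr[d], row$gdp_thousand_bs)
      }
    }
    out$per_capita <- pc
    out$per_gdp <- pg
  }
  class(out) <- "summary.bookkeeping"
  out
}

#' @export
print.summary.bookkeeping <- function(x, ...) {
  cat("National totals:\n")
  print(x$totals, row.names = FALSE)
  cat("\nBy department (annual tCO2/yr and national share):\n")
  print(x$by_department, row.names = FALSE)
  if (!is.null(x$per_capita)) {
    cat("\nPer capita (tCO2/person/yr):", round(x$per_capita, 1), "\n")
    cat("Per GDP (kg/Bs):", round(x$per_gdp, 1), "\n")
  }
  invisible(x)
}

#' @export
plot.bookkeeping <- function(x, ...) {
  yrs <- c(1991:2000, 2001:2010)
  flux <- c(x$annual[1, ], x$annual[2, ])
  graphics::barplot(flux / 1e6, names.arg = yrs, las = 2,
                    ylab = expression("Net " * CO[2] * " flux (Mt/yr)"),
                    col = ifelse(flux >= 0, "firebrick", "forestgreen"), ...)
  invisible(x)
}

#' @export
as.data.frame.bookkeeping <- function(x, ...) x$pixels
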