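#' Aboveground carbon of regrowth at a given age
#'
#' Evaluates the logistic regeneration curve
#' \eqn{CAR(a) = CAP / (1 + e^{\alpha - \beta a})} for one forest type.
#' The curve is calibrated so that carbon equals the agricultural level at
#' age 0 and 99\% of CAP at the type's recovery time (40 years for humid,
#' 35 for dry/seasonal forest).
#'
#' @param age Regrowth age in years (vectorised, must be non-negative).
#' @param params One forest type's parameters: a list (or one-row data
#'   frame) with \code{cap_agc}, \code{alpha}, \code{beta}.
#' @return Aboveground carbon, tC/ha.
#' @export
agb_regrowth <- function(age, params) {
  if (any(age < 0)) stop("regrowth age must be non-negative")
  params$cap_agc / (1 + exp(params$alpha - params$beta * age))
}

#' Regrowth age equivalent to a given aboveground carbon
#'
#' Inverts the logistic regeneration curve. Carbon at or below the age-0
#' level clamps to age 0; carbon at or above 99\% of CAP clamps to the
#' type's t99. Used to seed cohorts from observed carbon states.
#'
#' @param agc Aboveground carbon, tC/ha (vectorised).
#' @param params One forest type's parameters (needs \code{cap_agc},
#'   \code{alpha}, \code{beta}, \code{t99}).
#' @return Age in years.
#' @export
equivalent_age <- function(agc, params) {
  lo <- params$cap_agc / (1 + exp(params$alpha))       # value at age 0
  hi <- 0.99 * params$cap_agc
  age <- numeric(length(agc))
  mid <- agc > lo & agc < hi
  age[agc <= lo] <- 0
  age[agc >= hi] <- params$t99
  if (any(mid))
    age[mid] <- (params$alpha - log(params$cap_agc / agc[mid] - 1)) / params$beta
  age
}

#' Construct a soil carbon state
#'
#' @param soc_ref Undisturbed soil organic carbon in the top 100 cm, tC/ha.
#' @param soc_current Current SOC, tC/ha; defaults to the reference.
#' @param years_under_agriculture Cumulative years tilled (saturates at the
#'   loss horizon).
#' @return A list of class \code{soil_state} with the two densities, the
#'   agriculture-year counter and the recovery deficit.
#' @export
soil_state <- function(soc_ref, soc_current = soc_ref,
                       years_under_agriculture = 0) {
  stopifnot(soc_ref >= 0, soc_current >= 0, soc_current <= soc_ref + 1e-9)
  structure(list(soc_ref = soc_ref, soc_current = min(soc_current, soc_ref),
                 years_under_agriculture = years_under_agriculture,
                 recovery_deficit = soc_ref - min(soc_current, soc_ref)),
            class = "soil_state")
}

#' Advance a soil carbon state by one year
#'
#' Under agriculture, SOC declines linearly so that \code{soc_loss_frac} of
#' the reference stock is lost over \code{soc_loss_horizon} years, then stays
#' constant. On recovering land (abandoned fields, regrowth) SOC climbs back
#' at \code{recovery_slope_factor} times the decomposition slope — with the
#' default 0.5, recovery takes twice as long as the loss did. Undisturbed
#' land is unchanged. Re-cleared land resumes decomposition from its current
#' level, not from the reference.
#'
#' @param state A \code{\link{soil_state}}.
#' @param land_class One of \code{"agriculture"}, \code{"recovering"},
#'   \code{"undisturbed"}.
#' @param constants A \code{\link{global_constants}} object.
#' @return The soil state after one year.
#' @export
soc_step <- function(state, land_class = c("agriculture", "recovering",
                                           "undisturbed"),
                     constants = global_constants()) {
  land_class <- match.arg(land_class)
  slope <- constants$soc_loss_frac * state$soc_ref / constants$soc_loss_horizon
  floor_soc <- (1 - constants$soc_loss_frac) * state$soc_ref
  if (land_class == "agriculture") {
    if (state$years_under_agriculture < constants$soc_loss_horizon) {
      state$soc_current <- max(state$soc_current - slope, floor_soc)
      state$years_under_agriculture <- state$years_under_agriculture + 1
    }
  } else if (land_class == "recovering") {
    if (state$soc_current < state$soc_ref) {
      state$soc_current <- min(
        state$soc_current + constants$recovery_slope_factor * slope,
        state$soc_ref)
      if (state$soc_current >= state$soc_ref)
        state$years_under_agriculture <- 0
    }
  }
  state$recovery_deficit <- state$soc_ref - state$soc_current
  state
}

#' Aboveground carbon of degraded forest
#'
#' Degraded forest (selective logging, wildfire, natural disturbance on
#' never-cleared land) is assigned the aboveground carbon of regrowth of a
#' fixed equivalent age: 25 years in the central analysis (about 85\% of
#' mature carbon), 15 years in the severe-degradation sensitivity. Soil
#' carbon is left intact by the caller.
#'
#' @param params One forest type's parameters.
#' @param equiv_age Equivalent regrowth age, years (> 0).
#' @return Aboveground carbon, tC/ha.
#' @export
degraded_agc <- function(params, equiv_age = params$degraded_equiv_age) {
  stopifnot(equiv_age > 0)
  agb_regrowth(equiv_age, params)
}

#' Total per-hectare carbon stock of a land unit
#'
#' Sums aboveground carbon, root carbon (aboveground times the root:shoot
#' ratio) and soil organic carbon in the top 100 cm.
#'
#' @param agc Aboveground carbon, tC/ha.
#' @param soil A \code{\link{soil_state}} (or any list with
#'   \code{soc_current}).
#' @param params One forest type's parameters (needs \code{root_shoot}).
#' @return Total carbon, tC/ha.
#' @export
pixel_stock <- function(agc, soil, params) {
  stopifnot(all(agc >= 0))
  agc * (1 + params$root_shoot) + soil$soc_current
}
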