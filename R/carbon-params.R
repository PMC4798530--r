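#' Global constants of the bookkeeping model
#'
#' Returns the scalar constants shared by all forest types: the aboveground
#' carbon of agricultural land (cropland or pasture), the carbon fraction of
#' living biomass, the C-to-CO2 mass conversion, and the soil-organic-carbon
#' (SOC) decomposition/recovery rule.
#'
#' @param agri_agc Aboveground carbon of cropland/pasture, tC/ha.
#' @param carbon_fraction Carbon content per unit living biomass (dimensionless).
#' @param soc_loss_frac Fraction of reference SOC (top 100 cm) lost under
#'   continuous agriculture.
#' @param soc_loss_horizon Years over which that loss accrues linearly.
#' @param recovery_slope_factor SOC recovery slope relative to the
#'   decomposition slope (0.5 means recovery takes twice as long as loss).
#' @param other_veg_agc Aboveground carbon assigned to non-forest natural
#'   vegetation (savannah-like classes), tC/ha.
#'
#' @return A list of class \code{global_constants}.
#' @export
global_constants <- function(agri_agc = 5,
                             carbon_fraction = 0.5,
                             soc_loss_frac = 0.25,
                             soc_loss_horizon = 20,
                             recovery_slope_factor = 0.5,
                             other_veg_agc = 5) {
  stopifnot(agri_agc > 0, carbon_fraction > 0, soc_loss_horizon > 0,
            recovery_slope_factor > 0, other_veg_agc >= 0)
  if (soc_loss_frac <= 0 || soc_loss_frac >= 1)
    stop("soc_loss_frac must lie strictly between 0 and 1")
  structure(list(agri_agc = agri_agc,
                 carbon_fraction = carbon_fraction,
                 co2_per_c = 44 / 12,
                 soc_loss_frac = soc_loss_frac,
                 soc_loss_horizon = soc_loss_horizon,
                 recovery_slope_factor = recovery_slope_factor,
                 other_veg_agc = other_veg_agc),
            class = "global_constants")
}

#' Mature aboveground carbon from intact-pixel biomass samples
#'
#' Estimates the equilibrium aboveground carbon density (CAP) of a forest
#' type as a percentile of the aboveground biomass observed on nearly intact
#' pixels of that type, converted to carbon with the biomass carbon fraction.
#' The central analysis uses the median; the "clearing less dense forest
#' first" sensitivity uses the 25th percentile.
#'
#' @param biomass_samples Numeric vector of aboveground biomass values
#'   (t/ha) for nearly intact pixels of one forest type.
#' @param percentile Percentile in (0, 100).
#' @param carbon_fraction Carbon per unit biomass; default 0.5.
#' @param forest_type Optional label used in error messages.
#' @param type Quantile algorithm passed to \code{\link[stats]{quantile}};
#'   the default (7) interpolates linearly between closest order statistics.
#'
#' @return Mature aboveground carbon, tC/ha.
#' @export
estimate_cap <- function(biomass_samples, percentile = 50,
                         carbon_fraction = 0.5, forest_type = NULL,
                         type = 7) {
  lbl <- if (is.null(forest_type)) "" else paste0(" for forest type '", forest_type, "'")
  if (length(biomass_samples) == 0)
    stop("no intact-pixel biomass samples", lbl)
  if (anyNA(biomass_samples) || any(biomass_samples < 0))
    stop("biomass samples must be non-negative and non-missing", lbl)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  carbon_fraction *
    unname(stats::quantile(biomass_samples, percentile / 100, type = type))
}

#' Calibrate the logistic regrowth curve from its boundary conditions
#'
#' The aboveground carbon of regrowth of age \eqn{a} is
#' \deqn{CAR(a) = CAP / (1 + e^{\alpha - \beta a}).}
#' \code{calibrate_logistic} solves for \eqn{(\alpha, \beta)} from two
#' boundary conditions: the curve starts at the agricultural carbon level at
#' age 0 and reaches \code{target_frac} of CAP at age \code{t99}.
#'
#' @param cap_agc Mature aboveground carbon (the asymptote), tC/ha.
#' @param initial_agc Carbon at age 0 (agricultural land), tC/ha.
#' @param target_frac Fraction of CAP attained at \code{t99}; default 0.99.
#' @param t99 Years to reach \code{target_frac} of CAP.
#'
#' @return Named numeric vector \code{c(alpha =, beta =)}.
#' @export
#' @examples
#' ab <- calibrate_logistic(114, 5, 0.99, 40)
#' 114 / (1 + exp(ab["alpha"]))                 # 5 at age 0
#' 114 / (1 + exp(ab["alpha"] - ab["beta"] * 40)) # 0.99 * 114 at age 40
calibrate_logistic <- function(cap_agc, initial_agc = 5, target_frac = 0.99,
                               t99 = 40) {
  stopifnot(initial_agc > 0, t99 > 0, target_frac > 0, target_frac < 1)
  if (cap_agc <= initial_agc)
    stop("calibration undefined: mature carbon (", cap_agc,
         " tC/ha) must exceed the initial agricultural carbon (",
         initial_agc, " tC/ha)")
  alpha <- log(cap_agc / initial_agc - 1)
  beta <- (alpha - log(1 / target_frac - 1)) / t99
  c(alpha = alpha, beta = beta)
}

# Default forest-type table. Shares follow the national forest-type
# composition (Amazon dominant; Chaco, Chiquitano and Yungas each roughly a
# sixth; minor Andean types), median biomass spans the intact-forest spread,
# and t99 is 40 y for humid types, 35 y for dry/seasonal ones. Root:shoot
# defaults are IPCC-style: ~0.24 moist, ~0.28 dry forest.
default_forest_table <- function() {
  data.frame(
    name = c("amazon", "chiquitano", "chaco", "yungas", "flooded",
             "pantanal", "tucumano", "dry_interandean", "andean"),
    share = c(0.360, 0.160, 0.160, 0.150, 0.070,
              0.050, 0.040, 0.006, 0.004),
    median_biomass = c(285, 195, 150, 260, 220, 175, 205, 115, 140),
    t99 = c(40, 35, 35, 40, 40, 35, 35, 35, 35),
    root_shoot = c(0.24, 0.28, 0.28, 0.24, 0.24, 0.28, 0.28, 0.28, 0.28),
    stringsAsFactors = FALSE
  )
}

#' Build the full parameter set for the bookkeeping model
#'
#' Derives one row of curve parameters per forest type: mature aboveground
#' carbon (CAP) from intact-pixel biomass samples (or an explicit override),
#' the logistic coefficients calibrated from the age-0 and t99 boundary
#' conditions, the root:shoot ratio and the degraded-forest equivalent age.
#'
#' @param biomass_table Data frame with columns \code{forest_type},
#'   \code{biomass_t_ha} and optionally \code{intact_flag} (only rows with a
#'   true flag are used). May be \code{NULL} if \code{cap_override} covers
#'   every type.
#' @param config List of options: \code{percentile} (default 50),
#'   \code{percentile_type} (quantile algorithm, default 7),
#'   \code{degraded_equiv_age} (default 25), \code{forest_types} (data frame
#'   like \code{default_forest_table()}), \code{cap_override} (named vector
#'   of CAP values, tC/ha, taking precedence over samples),
#'   \code{alpha_override}/\code{beta_override} (named vectors replacing the
#'   calibrated coefficients, e.g. to drop in published parameters).
#' @param constants A \code{\link{global_constants}} object.
#'
#' @return An object of class \code{forest_params}: list with elements
#'   \code{types} (data frame: name, share, cap_agc, t99, alpha, beta,
#'   root_shoot, degraded_equiv_age) and \code{constants}.
#' @export
build_params <- function(biomass_table = NULL, config = list(),
                         constants = global_constants()) {
  ft <- config$forest_types
  if (is.null(ft)) ft <- default_forest_table()
  pct <- config$percentile %||% 50
  qtype <- config$percentile_type %||% 7
  deg_age <- config$degraded_equiv_age %||% 25
  ov <- config$cap_override

  if (!is.null(biomass_table)) {
    need <- c("forest_type", "biomass_t_ha")
    if (!all(need %in% names(biomass_table)))
      stop("biomass_table must have columns forest_type and biomass_t_ha")
    unknown <- setdiff(unique(biomass_table$forest_type), ft$name)
    if (length(unknown))
      stop("unknown forest type(s): ", paste(unknown, collapse = ", "),
           "; valid names are: ", paste(ft$name, collapse = ", "))
    if (!is.null(biomass_table$intact_flag))
      biomass_table <- biomass_table[as.logical(biomass_table$intact_flag), , drop = FALSE]
  }

  cap <- numeric(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    nm <- ft$name[i]
    if (!is.null(ov) && nm %in% names(ov)) {
      cap[i] <- ov[[nm]]
    } else {
      if (is.null(biomass_table))
        stop("no biomass samples and no cap_override for forest type '", nm, "'")
      smp <- biomass_table$biomass_t_ha[biomass_table$forest_type == nm]
      cap[i] <- estimate_cap(smp, pct, constants$carbon_fraction,
                             forest_type = nm, type = qtype)
    }
    if (cap[i] <= constants$agri_agc)
      stop("mature carbon for '", nm, "' (", signif(cap[i], 4),
           " tC/ha) does not exceed the agricultural carbon constant (",
           constants$agri_agc, " tC/ha); logistic calibration undefined")
  }

  ab <- t(vapply(seq_len(nrow(ft)), function(i)
    calibrate_logistic(cap[i], constants$agri_agc, 0.99, ft$t99[i]),
    numeric(2)))
  alpha <- ab[, 1]; beta <- ab[, 2]
  if (!is.null(config$alpha_override)) {
    j <- match(names(config$alpha_override), ft$name)
    alpha[j] <- config$alpha_override
  }
  if (!is.null(config$beta_override)) {
    j <- match(names(config$beta_override), ft$name)
    beta[j] <- config$beta_override
  }

  types <- data.frame(name = ft$name, share = ft$share, cap_agc = cap,
                      t99 = ft$t99, alpha = alpha, beta = beta,
                      root_shoot = ft$root_shoot,
                      degraded_equiv_age = deg_age,
                      stringsAsFactors = FALSE)
  structure(list(types = types, constants = constants,
                 percentile = pct, biomass_table = biomass_table,
                 config = config),
            class = "forest_params")
}

#' @export
print.forest_params <- function(x, ...) {
  cat("Forest carbon parameters (", nrow(x$types), " types, CAP from the ",
      x$percentile, "th biomass percentile)\n", sep = "")
  df <- x$types
  df$cap_agc <- round(df$cap_agc, 1)
  df$alpha <- round(df$alpha, 4)
  df$beta <- round(df$beta, 5)
  print(df, row.names = FALSE)
  cat("Area-weighted mature AGC:",
      round(sum(df$share * x$types$cap_agc) / sum(df$share), 1), "tC/ha\n")
  invisible(x)
}

#' Plot the aboveground carbon regeneration curves
#'
#' Draws carbon against regrowth age for every forest type, from the
#' agricultural starting level to the mature asymptote.
#'
#' @param x A \code{forest_params} object.
#' @param max_age Oldest age (years) to draw.
#' @param ... Passed to \code{matplot}.
#' @export
plot.forest_params <- function(x, max_age = 50, ...) {
  age <- 0:max_age
  m <- sapply(seq_len(nrow(x$types)), function(i)
    agb_regrowth(age, params_row(x, x$types$name[i])))
  graphics::matplot(age, m, type = "l", lty = 1, xlab = "Regrowth age (years)",
                    ylab = "Aboveground carbon (tC/ha)", ...)
  graphics::legend("bottomright", legend = x$types$name, col = seq_len(ncol(m)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

# Extract one forest type's parameters as a plain list.
params_row <- function(params, type_name) {
  i <- match(type_name, params$types$name)
  if (is.na(i)) stop("unknown forest type '", type_name, "'; valid names: ",
                     paste(params$types$name, collapse = ", "))
  as.list(params$types[i, ])
}

#' Export the regeneration curves as a table
#'
#' Tabulates aboveground carbon by age for each forest type, one column per
#' type, suitable for writing to CSV.
#'
#' @param params A \code{forest_params} object.
#' @param max_age Oldest age in years.
#' @param file Optional path; when given the table is written as CSV.
#' @return Data frame with an \code{age} column and one column per type.
#' @export
curve_table <- function(params, max_age = 50, file = NULL) {
  age <- 0:max_age
  out <- data.frame(age = age)
  for (nm in params$types$name)
    out[[nm]] <- agb_regrowth(age, params_row(params, nm))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
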