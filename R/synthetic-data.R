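#' Configuration for the synthetic landscape generator
#'
#' Describes the statistical structure of a synthetic study region: the
#' forest-type composition with per-type biomass distributions (right-skewed,
#' lognormal), the spatial range of soil organic carbon, the initial
#' land-cover shares, the two decadal cover-transition matrices (including
#' "odd" transitions such as other vegetation observed later as forest), and
#' an administrative partition with population and GDP per period.
#'
#' @param n_pixels Number of grid pixels.
#' @param seed Random seed; generation is bit-reproducible given the seed.
#' @param area_ha Nominal pixel area, ha (10 x 10 km pixels by default).
#' @param forest_types Data frame with columns \code{name}, \code{share},
#'   \code{median_biomass} (t/ha), \code{t99}, \code{root_shoot}.
#' @param biomass_sdlog Lognormal dispersion of intact biomass around the
#'   type median.
#' @param soc_range Range (tC/ha) of department-level mean soil carbon.
#' @param soc_sd Within-department pixel standard deviation, tC/ha.
#' @param cover_shares_1990 Named shares over the five cover classes.
#' @param trans_90_00,trans_00_10 5 x 5 row-stochastic matrices over
#'   \code{c("forest","regrowth","agriculture","other_vegetation",
#'   "nonvegetated")}.
#' @param departments Data frame: \code{name}, \code{weight} (pixel
#'   allocation), \code{pop_1990_2000}, \code{pop_2000_2010},
#'   \code{gdp_1990_2000}, \code{gdp_2000_2010} (GDP in thousands).
#' @param n_munis Municipalities per department.
#' @return An object of class \code{landscape_config}.
#' @export
landscape_config <- function(n_pixels = 1000, seed = 1, area_ha = 10000,
                             forest_types = default_forest_table(),
                             biomass_sdlog = 0.35,
                             soc_range = c(30, 140), soc_sd = 12,
                             cover_shares_1990 = c(
                               forest = 0.52, regrowth = 0.01,
                               agriculture = 0.02,
                               other_vegetation = 0.40,
                               nonvegetated = 0.05),
                             trans_90_00 = default_transitions(),
                             trans_00_10 = default_transitions(),
                             departments = default_departments(),
                             n_munis = 3) {
  cfg <- structure(list(n_pixels = n_pixels, seed = seed, area_ha = area_ha,
                        forest_types = forest_types,
                        biomass_sdlog = biomass_sdlog,
                        soc_range = soc_range, soc_sd = soc_sd,
                        cover_shares_1990 = cover_shares_1990,
                        trans_90_00 = trans_90_00,
                        trans_00_10 = trans_00_10,
                        departments = departments, n_munis = n_munis),
                   class = "landscape_config")
  validate_landscape_config(cfg)
  cfg
}

validate_landscape_config <- function(cfg) {
  cls <- .COVER_CLASSES
  if (!isTRUE(all.equal(sum(cfg$cover_shares_1990), 1, tolerance = 1e-9)) ||
      !setequal(names(cfg$cover_shares_1990), cls))
    stop("cover_shares_1990 must be named over the five cover classes and sum to 1")
  for (nm in c("trans_90_00", "trans_00_10")) {
    P <- cfg[[nm]]
    if (!all(dim(P) == c(5, 5)) ||
        !isTRUE(all.equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-9)) ||
        any(P < 0))
      stop(nm, " must be a 5 x 5 row-stochastic matrix")
  }
  if (!isTRUE(all.equal(sum(cfg$forest_types$share), 1, tolerance = 1e-6)))
    stop("forest type shares must sum to 1")
  invisible(cfg)
}

#' Default decadal cover-transition matrix
#'
#' A moderate-deforestation transition structure: most forest persists, a
#' few percent is cleared for agriculture per decade, small fractions are
#' degraded or burn into other vegetation, abandoned fields regenerate, and
#' rare odd transitions (other vegetation observed later as forest) occur.
#'
#' @return 5 x 5 row-stochastic matrix with dimnames over the cover classes.
#' @export
default_transitions <- function() {
  cls <- .COVER_CLASSES
  P <- matrix(0, 5, 5, dimnames = list(cls, cls))
  P["forest", ] <- c(0.960, 0.008, 0.026, 0.0055, 0.0005)
  P["regrowth", ] <- c(0.10, 0.80, 0.09, 0.01, 0)
  P["agriculture", ] <- c(0.01, 0.15, 0.82, 0.02, 0)
  P["other_vegetation", ] <- c(0.005, 0, 0.010, 0.985, 0)
  P["nonvegetated", ] <- c(0, 0, 0, 0, 1)
  P
}

default_departments <- function() {
  data.frame(
    name = c("santa_cruz", "la_paz", "cochabamba", "beni", "pando",
             "chuquisaca", "tarija", "potosi", "oruro"),
    weight = c(0.34, 0.12, 0.10, 0.20, 0.06, 0.05, 0.04, 0.05, 0.04),
    pop_1990_2000 = c(1812000, 2032000, 1283000, 313000, 46000,
                      512000, 363000, 687000, 362000),
    pop_2000_2010 = c(2433000, 2486000, 1596000, 399000, 75000,
                      576000, 459000, 745000, 420000),
    gdp_1990_2000 = c(5262000, 4852000, 3314000, 692000, 148000,
                      1021000, 946000, 1035000, 980000),
    gdp_2000_2010 = c(7724000, 6627000, 4652000, 967000, 250000,
                      1357000, 1861000, 1490000, 1330000),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic landscape
#'
#' Samples a pixel grid, the intact-pixel biomass table and the
#' admin-statistics table from a \code{\link{landscape_config}}. Pixels are
#' assigned a department, municipality and forest type; intact biomass is
#' lognormal around the type median; soil carbon varies between and within
#' departments; land cover follows the initial shares and then the two
#' decadal transition matrices, sampled independently per pixel. Pixels
#' observed as forest at all three epochs are flagged nearly intact and feed
#' the mature-carbon percentiles.
#'
#' @param config A \code{\link{landscape_config}}.
#' @return List with \code{grid} (pixel records), \code{biomass}
#'   (\code{forest_type}, \code{biomass_t_ha}, \code{intact_flag}) and
#'   \code{admin} (unit, level, period, population, gdp_thousand_bs).
#' @export
gen_landscape <- function(config) {
  validate_landscape_config(config)
  set.seed(config$seed)
  n <- config$n_pixels
  cls <- .COVER_CLASSES
  dep <- config$departments
  department <- sample(dep$name, n, replace = TRUE,
                       prob = dep$weight / sum(dep$weight))
  municipality <- paste0(department, "_m",
                         sample.int(config$n_munis, n, replace = TRUE))
  ft <- config$forest_types
  forest_type <- sample(ft$name, n, replace = TRUE,
                        prob = ft$share / sum(ft$share))
  mlog <- log(ft$median_biomass)[match(forest_type, ft$name)]
  biomass <- exp(stats::rnorm(n, mlog, config$biomass_sdlog))

  dep_soc <- stats::runif(nrow(dep), config$soc_range[1], config$soc_range[2])
  soc <- stats::rnorm(n, dep_soc[match(department, dep$name)], config$soc_sd)
  soc <- pmin(pmax(soc, config$soc_range[1]), config$soc_range[2])

  cover_1990 <- sample(cls, n, replace = TRUE,
                       prob = config$cover_shares_1990[cls])
  cover_2000 <- sample_transition(cover_1990, config$trans_90_00)
  cover_2010 <- sample_transition(cover_2000, config$trans_00_10)

  woody <- cover_1990 %in% c("forest", "regrowth") |
    cover_2000 %in% c("forest", "regrowth") |
    cover_2010 %in% c("forest", "regrowth")
  grid <- data.frame(
    pixel_id = sprintf("px%05d", seq_len(n)),
    area_ha = config$area_ha,
    forest_type = ifelse(woody, forest_type, NA_character_),
    agb_biomass_t_ha = ifelse(woody, biomass, NA_real_),
    soc_ref = soc,
    department = department, municipality = municipality,
    cover_1990 = cover_1990, cover_2000 = cover_2000,
    cover_2010 = cover_2010, stringsAsFactors = FALSE)
  validate_grid(grid)

  intact <- cover_1990 == "forest" & cover_2000 == "forest" &
    cover_2010 == "forest"
  biomass_tab <- data.frame(forest_type = forest_type,
                            biomass_t_ha = biomass,
                            intact_flag = intact,
                            stringsAsFactors = FALSE)[woody | intact, ]
  # guarantee a minimal intact reference sample per type, so rare types
  # (tiny area shares) still support a percentile estimate at small n
  minref <- config$min_reference_samples %||% 30
  for (i in seq_len(nrow(ft))) {
    have <- sum(biomass_tab$intact_flag & biomass_tab$forest_type == ft$name[i])
    if (have < minref) {
      extra <- minref - have
      biomass_tab <- rbind(biomass_tab, data.frame(
        forest_type = ft$name[i],
        biomass_t_ha = exp(stats::rnorm(extra, log(ft$median_biomass[i]),
                                        config$biomass_sdlog)),
        intact_flag = TRUE, stringsAsFactors = FALSE))
    }
  }

  periods <- c("1990-2000", "2000-2010")
  admin <- rbind(
    data.frame(unit = rep(dep$name, 2), level = "department",
               period = rep(periods, each = nrow(dep)),
               population = c(dep$pop_1990_2000, dep$pop_2000_2010),
               gdp_thousand_bs = c(dep$gdp_1990_2000, dep$gdp_2000_2010),
               stringsAsFactors = FALSE),
    data.frame(unit = "national", level = "national", period = periods,
               population = c(sum(dep$pop_1990_2000),
                              sum(dep$pop_2000_2010)),
               gdp_thousand_bs = c(sum(dep$gdp_1990_2000),
                                   sum(dep$gdp_2000_2010)),
               stringsAsFactors = FALSE))
  munis <- unique(data.frame(department = department,
                             municipality = municipality,
                             stringsAsFactors = FALSE))
  nm <- stats::ave(seq_len(nrow(munis)), munis$department, FUN = length)
  di <- match(munis$department, dep$name)
  admin <- rbind(admin, do.call(rbind, lapply(periods, function(pd) {
    popcol <- if (pd == periods[1]) "pop_1990_2000" else "pop_2000_2010"
    gdpcol <- if (pd == periods[1]) "gdp_1990_2000" else "gdp_2000_2010"
    data.frame(unit = munis$municipality, level = "municipality",
               period = pd, population = dep[[popcol]][di] / nm,
               gdp_thousand_bs = dep[[gdpcol]][di] / nm,
               stringsAsFactors = FALSE)
  })))
  list(grid = grid, biomass = biomass_tab, admin = admin)
}

sample_transition <- function(cover, P) {
  cls <- colnames(P)
  out <- character(length(cover))
  for (cl in unique(cover)) {
    i <- which(cover == cl)
    out[i] <- sample(cls, length(i), replace = TRUE, prob = P[cl, ])
  }
  out
}

#' Expected cover shares at each epoch
#'
#' Propagates the configured 1990 shares through the two transition
#' matrices; the exact expectation the sampled landscape converges to.
#'
#' @param config A \code{\link{landscape_config}}.
#' @return 3 x 5 matrix (epochs 1990/2000/2010 by cover class).
#' @export
expected_cover_shares <- function(config) {
  cls <- .COVER_CLASSES
  s0 <- config$cover_shares_1990[cls]
  s1 <- drop(s0 %*% config$trans_90_00[cls, cls])
  s2 <- drop(s1 %*% config$trans_00_10[cls, cls])
  m <- rbind(`1990` = s0, `2000` = s1, `2010` = s2)
  colnames(m) <- cls
  m
}

#' National-scale preset landscape configuration
#'
#' Builds a \code{\link{landscape_config}} whose expected epoch-level forest
#' areas scale (at reduced pixel count) to the national 56.8 / 55.0 / 52.6
#' million-hectare trajectory over 1990/2000/2010 on a 108.4 Mha territory,
#' and whose share-weighted median mature carbon is 114 tC/ha. Transition
#' rows are solved so the expected forest shares hit the trajectory exactly,
#' with odd transitions (forest to regrowth without clearing, other
#' vegetation later observed as forest) at their observed decade-2 rates.
#' National population and GDP follow the published mid-period values.
#'
#' @param n_pixels Number of pixels (each 10,000 ha; the full country would
#'   be about 10,840).
#' @param seed Random seed.
#' @return A \code{landscape_config}.
#' @export
gen_national_like <- function(n_pixels = 2000, seed = 1) {
  total_mha <- 108.4
  f <- c(56.8, 55.0, 52.6) / total_mha
  s0 <- c(forest = f[1], regrowth = 1.0 / total_mha,
          agriculture = 1.9 / total_mha, other_vegetation = 0,
          nonvegetated = 0.05)
  s0["other_vegetation"] <- 1 - sum(s0)

  ft <- default_forest_table()
  w <- sum(ft$share * 0.5 * ft$median_biomass) / sum(ft$share)
  ft$median_biomass <- ft$median_biomass * 114 / w

  cls <- .COVER_CLASSES
  mk <- function(p_fr, p_fo, p_fn, p_of, shares, f_next) {
    P <- matrix(0, 5, 5, dimnames = list(cls, cls))
    P["regrowth", ] <- c(0.10, 0.80, 0.09, 0.01, 0)
    P["agriculture", ] <- c(0.01, 0.17, 0.80, 0.02, 0)
    P["other_vegetation", ] <- c(p_of, 0, 0.01, 1 - p_of - 0.01, 0)
    P["nonvegetated", "nonvegetated"] <- 1
    inflow <- shares["regrowth"] * P["regrowth", "forest"] +
      shares["agriculture"] * P["agriculture", "forest"] +
      shares["other_vegetation"] * p_of
    p_ff <- (f_next - inflow) / shares["forest"]
    p_fa <- 1 - p_ff - p_fr - p_fo - p_fn
    if (p_fa < 0 || p_ff < 0)
      stop("infeasible forest trajectory for these transition rates")
    P["forest", ] <- c(p_ff, p_fr, p_fa, p_fo, p_fn)
    P
  }
  P1 <- mk(p_fr = 0.004, p_fo = 0.004, p_fn = 0.0005, p_of = 0.004,
           shares = s0, f_next = f[2])
  s1 <- drop(s0 %*% P1)
  # decade 2: 0.8 Mha forest->regrowth, 1.27 Mha forest->other vegetation,
  # 1.33 Mha other vegetation->forest, as fractions of the source areas
  P2 <- mk(p_fr = 0.8 / 55.0, p_fo = 1.27 / 55.0, p_fn = 0.0005,
           p_of = 1.33 / (s1["other_vegetation"] * total_mha),
           shares = s1, f_next = f[3])

  dep <- default_departments()
  scale_to <- function(x, target) x * target / sum(x)
  dep$pop_1990_2000 <- scale_to(dep$pop_1990_2000, 6987201)
  dep$pop_2000_2010 <- scale_to(dep$pop_2000_2010, 8873150)
  dep$gdp_1990_2000 <- scale_to(dep$gdp_1990_2000, 18626778)
  dep$gdp_2000_2010 <- scale_to(dep$gdp_2000_2010, 26657738)

  landscape_config(n_pixels = n_pixels, seed = seed,
                   forest_types = ft,
                   cover_shares_1990 = s0,
                   trans_90_00 = P1, trans_00_10 = P2,
                   departments = dep)
}
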