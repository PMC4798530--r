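test_that("scenario_spec validates its knobs and pins the baseline", {
  expect_error(scenario_spec("x", pasture_share = 1.2), "\\[0, 1\\]")
  expect_error(scenario_spec("x", cap_percentile = 0), "percentile")
  expect_error(scenario_spec("baseline", soc_loss_frac = 0.35),
               "baseline")
  expect_silent(scenario_spec("baseline"))
  expect_equal(length(preset_scenarios()), 8)
})

test_that("apply_scenario changes only the named knobs", {
  base <- list(percentile = 50, soc_loss_frac = 0.25,
               degraded_equiv_age = 25, pasture_share = 0,
               cohort_rule = "uniform")
  out <- apply_scenario(base, scenario_spec("baseline"))
  expect_equal(out[names(base)], base)
  out <- apply_scenario(base, scenario_spec("pasture_20",
                                            pasture_share = 0.2))
  expect_equal(out$pasture_share, 0.2)
  expect_equal(out$percentile, 50)
  expect_equal(out$cohort_rule, "uniform")
})

test_that("soil loss fraction of 0.35 leaves 65% of soil carbon after 20 years", {
  cst <- global_constants(soc_loss_frac = 0.35)
  s <- soil_state(100)
  for (i in 1:20) s <- soc_step(s, "agriculture", cst)
  expect_equal(s$soc_current, 65)
})

test_that("pasture share shields soil carbon on the pasture fraction", {
  params <- ref_params()
  px <- make_pixel("forest", "agriculture", "agriculture")
  base <- run_pixel(px, params)
  past <- run_pixel(px, params, scenario = scenario_spec(
    "pasture_20", pasture_share = 0.2))
  expect_lt(past$period_total[1], base$period_total[1])
  # aboveground loss identical; exactly 20% of the soil loss is avoided
  soc_base <- base$period_total[1] + base$period_total[2]
  soc_past <- past$period_total[1] + past$period_total[2]
  agb_loss <- (114 - 5) * px$area_ha * 44 / 12
  expect_equal((soc_past - agb_loss) / (soc_base - agb_loss), 0.8,
               tolerance = 1e-6)
})

test_that("erosion flux follows the stated rates and depletes the stock", {
  grid <- make_pixel("other_vegetation", "other_vegetation",
                     "other_vegetation", forest_type = NA,
                     soc_ref = 100, area_ha = 1)
  params <- ref_params()
  spec <- scenario_spec("erosion", erosion = list(
    enabled = TRUE, eroding_share_of_nonforest = 1))
  ef <- erosion_flux(grid, params, spec)
  # year 1: 1 tC eroded, 1.5% oxidised
  expect_equal(ef$annual[1], 0.015 * 1 * 44 / 12, tolerance = 1e-12)
  expect_equal(ef$annual[2] / ef$annual[1], 0.99, tolerance = 1e-12)
  # zero eroding share -> zero flux
  spec0 <- scenario_spec("e0", erosion = list(
    enabled = TRUE, eroding_share_of_nonforest = 0))
  expect_equal(erosion_flux(grid, params, spec0)$total, 0)
  # constant-stock approximation within 5% of the depleting recursion
  specc <- scenario_spec("ec", erosion = list(
    enabled = TRUE, eroding_share_of_nonforest = 1, mode = "constant"))
  tot_c <- erosion_flux(grid, params, specc)$total
  expect_equal(tot_c, 10 * 0.015 * 0.01 * 100 * 44 / 12, tolerance = 1e-12)
  expect_lt(abs(tot_c - ef$total) / tot_c, 0.05)
  # forested land never erodes
  gforest <- make_pixel("forest", "forest", "forest")
  expect_equal(erosion_flux(gforest, params, spec)$total, 0)
})

test_that("the mature-forest sink absorbs 4% of CAP per decade", {
  grid <- make_pixel("forest", "forest", "forest", area_ha = 1)
  params <- ref_params()
  spec <- scenario_spec("sink", mature_sink = list(enabled = TRUE))
  sf <- mature_sink_flux(grid, params, spec)
  expect_equal(sf$total, -0.04 * 114 * 44 / 12, tolerance = 1e-12)
  expect_equal(sf$annual, rep(sf$total / 10, 10))
  cleared <- make_pixel("forest", "agriculture", "agriculture")
  expect_equal(mature_sink_flux(cleared, params, spec,
                                period = "1990-2000")$total, 0)
})

test_that("tier1 is the committed-emissions closed form", {
  expect_equal(tier1(2431200, 0, 114, 10), 243120 * 114 * 44 / 12)
  expect_equal(tier1(1e6, 1e6, 114, 10), 0)
  expect_equal(tier1(2e6, 0, 114, 10), 2 * tier1(1e6, 0, 114, 10))
  # forest gain gives a negative emission
  expect_lt(tier1(1e6, 2e6, 114, 10), 0)
  expect_error(tier1(1, 0, 114, 0))
})

test_that("scenario emissions order matches the published directions", {
  land <- small_landscape(n = 250, seed = 21)
  params <- build_params(land$biomass, list(percentile = 50))
  tab <- run_scenarios(land$grid, params, admin = land$admin)
  e <- stats::setNames(tab$annual_tco2_2000_2010, tab$scenario)
  expect_lt(e[["clearing_less_dense_first"]], e[["baseline"]])
  expect_lt(e[["pasture_20"]], e[["baseline"]])
  expect_gt(e[["aggressive_agriculture"]], e[["baseline"]])
  expect_gt(e[["severely_degraded"]], e[["baseline"]])
  expect_gt(e[["erosion"]], e[["baseline"]])
  expect_lt(e[["mature_sink"]], e[["baseline"]])
  expect_lt(e[["static_land_combined"]], e[["baseline"]])
  expect_equal(nrow(tab), 8)
  expect_true(all(c("per_capita_1990_2000", "per_capita_2000_2010")
                  %in% names(tab)))
})

test_that("tier1 matches the engine's committed bound on a degenerate grid", {
  # no regrowth, no degradation, no soil carbon, root:shoot zero: in the
  # long run the engine books exactly the committed aboveground emission
  params <- ref_params(root_shoot = 0)
  px <- make_pixel("forest", "agriculture", "agriculture", soc_ref = 0)
  res <- run_pixel(px, params)
  committed_total <- tier1(px$area_ha, 0, 114 - 5, 10) * 10
  expect_equal(sum(res$period_total), committed_total, tolerance = 1e-9)
})
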