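test_that("agb_regrowth honours its boundaries and the 25-year anchor", {
  p <- ref_type()
  expect_equal(agb_regrowth(0, p), 5, tolerance = 1e-12)
  expect_equal(agb_regrowth(40, p), 0.99 * 114, tolerance = 1e-12)
  # 25-year regrowth carries ~85% of mature carbon
  expect_equal(agb_regrowth(25, p) / 114, 0.85, tolerance = 0.01)
  expect_error(agb_regrowth(-1, p), "non-negative")
})

test_that("agb_regrowth is strictly increasing, bounded, steepest at alpha/beta", {
  p <- ref_type()
  ages <- 0:120
  v <- agb_regrowth(ages, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < p$cap_agc))
  d <- diff(agb_regrowth(seq(0, 40, by = 0.1), p))
  inflect <- seq(0, 40, by = 0.1)[which.max(d)]
  expect_equal(inflect, p$alpha / p$beta, tolerance = 0.15)
})

test_that("equivalent_age inverts the curve and clamps at the ends", {
  p <- ref_type()
  expect_equal(equivalent_age(5, p), 0)
  expect_equal(equivalent_age(2, p), 0)          # below the floor: clamp
  expect_equal(equivalent_age(0.995 * 114, p), 40)
  a <- equivalent_age(agb_regrowth(17.3, p), p)
  expect_equal(a, 17.3, tolerance = 1e-6)
  # independent bisection oracle for the 85% anchor
  bisect <- function(target, lo = 0, hi = 40) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (agb_regrowth(mid, p) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(equivalent_age(0.85 * 114, p), bisect(0.85 * 114),
               tolerance = 1e-6)
  expect_equal(equivalent_age(0.85 * 114, p), 25, tolerance = 0.6)
})

test_that("round trip age -> carbon -> age is the identity on [0, t99]", {
  p <- ref_type()
  ages <- seq(0.5, 39.5, by = 0.5)
  expect_equal(equivalent_age(agb_regrowth(ages, p), p), ages,
               tolerance = 1e-8)
})

test_that("soil carbon declines 25% over 20 years and recovers in twice the time", {
  s <- soil_state(100)
  for (i in 1:10) s <- soc_step(s, "agriculture")
  expect_equal(s$soc_current, 87.5)
  for (i in 1:10) s <- soc_step(s, "agriculture")
  expect_equal(s$soc_current, 75)
  # no further loss beyond the horizon
  s2 <- soc_step(s, "agriculture")
  expect_equal(s2$soc_current, 75)
  # recovery at half the slope: exactly 40 years back to the reference
  yrs <- 0
  while (s$soc_current < s$soc_ref) {
    s <- soc_step(s, "recovering")
    yrs <- yrs + 1
    expect_lt(yrs, 200)
  }
  expect_equal(yrs, 40)
  expect_equal(s$recovery_deficit, 0)
})

test_that("recovery takes twice the decomposition duration for any spell", {
  for (dur in c(4, 9, 15, 20)) {
    s <- soil_state(80)
    for (i in seq_len(dur)) s <- soc_step(s, "agriculture")
    lost <- 80 - s$soc_current
    expect_equal(lost, 0.25 * 80 * dur / 20, tolerance = 1e-12)
    yrs <- 0
    while (s$soc_current < s$soc_ref) {
      s <- soc_step(s, "recovering")
      yrs <- yrs + 1
    }
    expect_equal(yrs, 2 * dur)
  }
})

test_that("undisturbed soil is unchanged and nothing goes negative", {
  s <- soil_state(60, soc_current = 50, years_under_agriculture = 20)
  expect_equal(soc_step(s, "undisturbed")$soc_current, 50)
  s <- soil_state(10)
  for (i in 1:50) s <- soc_step(s, "agriculture")
  expect_gte(s$soc_current, 0.75 * 10 - 1e-12)
})

test_that("degraded forest carries fixed-age regrowth carbon", {
  p <- ref_type()
  expect_equal(degraded_agc(p, 25) / 114, 0.85, tolerance = 0.01)
  expect_equal(degraded_agc(p, 15) / 114, 0.45, tolerance = 0.01)
  expect_equal(degraded_agc(p, 40), 0.99 * 114, tolerance = 1e-9)
  expect_equal(degraded_agc(p), agb_regrowth(25, p))
  expect_error(degraded_agc(p, 0))
})

test_that("pixel_stock assembles aboveground, root and soil carbon", {
  p <- list(root_shoot = 0.2)
  expect_equal(pixel_stock(100, list(soc_current = 80), p), 200)
  expect_equal(pixel_stock(0, list(soc_current = 50), p), 50)
  expect_error(pixel_stock(-1, list(soc_current = 0), p))
})

test_that("stock difference times 44/12 is the instantaneous clearing emission", {
  # mass-balance oracle: one cohort cleared in a single event
  params <- ref_params(root_shoot = 0.24)
  p <- ref_type(root_shoot = 0.24)
  cst <- params$constants
  co <- init_state(make_pixel("forest", "forest", "forest"), params)
  stock0 <- pixel_stock(co[1, "agc"], list(soc_current = co[1, "soc"]), p)
  co1 <- step_year(co, list(list(from = "forest", to = "agriculture",
                                 area_frac = 1)), p, cst, 100)
  stock1 <- sum(co1[, "frac"] *
                  pixel_stock(co1[, "agc"],
                              list(soc_current = co1[, "soc"]), p))
  expect_equal(unname((stock0 - stock1) * 44 / 12),
               (114 - 5) * 1.24 * 44 / 12, tolerance = 1e-9)
})
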