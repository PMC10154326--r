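test_that("geometry derives volumes and isometric dimensions from mass", {
  g <- geometry_from_mass(0.00875, 875)
  vol <- function(p) if (p$shape == "cylinder")
    pi * p$diameter_m^2 / 4 * p$length_m else 4 / 3 * pi * prod(p$semi_axes_m)
  total <- sum(vapply(g, vol, numeric(1)))
  expect_equal(total, 1.0e-5, tolerance = 1e-9)
  expect_equal((3 * total / (4 * pi))^(1 / 3), 0.013365, tolerance = 1e-4)
  # doubling mass scales every linear dimension by 2^(1/3)
  g2 <- geometry_from_mass(2 * 0.00875, 875)
  expect_equal(g2$torso$semi_axes_m / g$torso$semi_axes_m,
               rep(2^(1 / 3), 3))
  expect_equal(g2$leg$diameter_m / g$leg$diameter_m, 2^(1 / 3))
  expect_error(geometry_from_mass(-1, 875))
})

test_that("measured dimensions are kept within the 5% density rule", {
  base <- geometry_from_mass(0.170, 875)
  # dims implying ~880 kg/m3 (within 5%): kept unchanged
  d880 <- base$leg$diameter_m * (875 / 880)^(1 / 3)
  l880 <- base$leg$length_m * (875 / 880)^(1 / 3)
  g <- geometry_from_mass(0.170, 875,
                          measured = list(leg = list(diameter_m = d880,
                                                     length_m = l880)))
  expect_equal(g$leg$diameter_m, d880)
  # dims implying a 30% heavier density: rescaled back to the target volume
  dbad <- base$leg$diameter_m * (875 / 1140)^(1 / 3)
  lbad <- base$leg$length_m * (875 / 1140)^(1 / 3)
  g2 <- geometry_from_mass(0.170, 875,
                           measured = list(leg = list(diameter_m = dbad,
                                                      length_m = lbad)))
  expect_equal(pi * g2$leg$diameter_m^2 / 4 * g2$leg$length_m,
               pi * base$leg$diameter_m^2 / 4 * base$leg$length_m,
               tolerance = 1e-9)
})

test_that("insulation resistance responds to the cascade controls", {
  sp <- parakeet(); ctl <- tr_control()
  torso <- sp$parts$torso
  st1 <- thermo_state(1.0, 1.0, traits = sp, control = ctl)
  st15 <- thermo_state(1.0, 1.5, traits = sp, control = ctl)
  expect_gt(insulation_resistance(torso, st15, 1.0, sp, ctl),
            insulation_resistance(torso, st1, 1.0, sp, ctl))
  # flesh term scales exactly with 1/k_flesh
  leg <- sp$parts$leg
  no_fat <- sp; no_fat$fat_fraction <- 0
  r_lo <- insulation_resistance(leg, st1, 0.41, no_fat, ctl)
  r_hi <- insulation_resistance(leg, st1, 2.80, no_fat, ctl)
  expect_equal(r_hi / r_lo, 0.41 / 2.80, tolerance = 1e-12)
  # bare parts carry no plumage term: resistance is the flesh layer alone
  expect_equal(r_lo, leg$flesh_depth_m / 0.41, tolerance = 1e-12)
})

test_that("convective coefficient follows the documented power law", {
  ctl <- tr_control()
  d <- 0.04
  expect_equal(convective_coefficient(0, d, control = ctl),
               ctl$free_nu * ctl$k_air / d)
  h1 <- convective_coefficient(1, d, control = ctl)
  h4 <- convective_coefficient(4, d, control = ctl)
  expect_equal(h4 / h1, 2.0, tolerance = 1e-12)
  expect_gt(convective_coefficient(3, 0.02, control = ctl),
            convective_coefficient(3, 0.08, control = ctl))
  expect_error(convective_coefficient(-1, d))
})

test_that("zero thermal gradient needs zero metabolic heat", {
  sp <- parakeet()
  ctl <- tr_control(solar_enabled = FALSE, evap_enabled = FALSE)
  mc <- mild_hour(air = sp$core_temp_c, sky = sp$core_temp_c,
                  ground = sp$core_temp_c, solar = 0)
  res <- solve_heat_balance(sp, neutral_state(sp, ctl), mc, ctl)
  expect_equal(res$m_required_w, 0, tolerance = 1e-12)
})

test_that("solver matches the series-resistance closed form on a single
           cylinder with a fixed convective coefficient", {
  ctl <- tr_control(solar_enabled = FALSE, evap_enabled = FALSE,
                    free_nu = 4000)   # floor dominates: h_c fixed
  sp <- bird_traits("cyl", mass_kg = 0.2, core_temp_c = 40, bmr_w = 1)
  cyl <- sp$parts$neck
  sp$parts <- list(neck = cyl)
  st <- thermo_state(1.2, 1.3, traits = sp, control = ctl)
  mc <- mild_hour(air = 0, sky = 0, ground = 0, wind = 3, active = FALSE)
  res <- solve_heat_balance(sp, st, mc, ctl)
  hr <- 4 * ctl$emissivity * ctl$sigma * (ctl$lw_lin_temp_c + 273.15)^3
  hc <- ctl$free_nu * ctl$k_air / cyl$d_char_m
  r_tot <- insulation_resistance(cyl, st, st$k_flesh, sp, ctl) +
    1 / (hc + hr)
  expect_equal(res$m_required_w,
               (40 - 0) / r_tot * cyl$area_eff_m2,
               tolerance = 1e-9)
  # warmer air strictly reduces the requirement
  res20 <- solve_heat_balance(sp, st, mild_hour(air = 20, sky = 20,
                                                ground = 20, wind = 3), ctl)
  expect_lt(res20$m_required_w, res$m_required_w)
})

test_that("required rate is monotone in air temperature, wind and
           feather depth", {
  sp <- parakeet()
  ctl <- tr_control(solar_enabled = FALSE, evap_enabled = FALSE)
  st <- neutral_state(sp, ctl)
  m_of_ta <- vapply(seq(-40, 40, 5), function(ta)
    solve_heat_balance(sp, st, mild_hour(air = ta, sky = ta, ground = ta),
                       ctl)$m_required_w, numeric(1))
  expect_true(all(diff(m_of_ta) <= 1e-12))
  m_of_wind <- vapply(c(0, 1, 3, 6, 10), function(w)
    solve_heat_balance(sp, st, mild_hour(air = 0, sky = 0, ground = 0,
                                         wind = w), ctl)$m_required_w,
    numeric(1))
  expect_true(all(diff(m_of_wind) >= -1e-12))
  m_of_depth <- vapply(c(0.8, 1.0, 1.3, 1.6), function(fs) {
    spd <- bird_traits("v", sp$mass_kg, sp$core_temp_c, sp$bmr_w,
                       feather_depth_scale = fs)
    solve_heat_balance(spd, neutral_state(spd, ctl),
                       mild_hour(air = 0, sky = 0, ground = 0),
                       ctl)$m_required_w
  }, numeric(1))
  expect_true(all(diff(m_of_depth) < 0))
})

test_that("the cascade is ordered, stable and idempotent", {
  sp <- parakeet()
  ctl <- tr_control(solar_enabled = FALSE, evap_enabled = FALSE)
  bmr <- sp$bmr_w
  # a condition already in band at neutral: state returned unchanged
  neutral <- neutral_state(sp, ctl)
  ta_grid <- seq(-30, 41, 0.1)
  m_neutral <- vapply(ta_grid, function(ta)
    solve_heat_balance(sp, neutral, mild_hour(air = ta, sky = ta,
                                              ground = ta, active = TRUE),
                       ctl)$m_required_w, numeric(1))
  ta_ok <- ta_grid[abs(m_neutral - 2.5 * bmr) <= 0.05 * 2.5 * bmr][1]
  res <- thermoregulate(sp, mild_hour(air = ta_ok, sky = ta_ok,
                                      ground = ta_ok, active = TRUE),
                        2.5 * bmr, ctl)
  expect_equal(res$state$k_flesh, neutral$k_flesh)
  expect_equal(res$state$plumage_depth_multiplier, 1)
  # moderately cold: vasoconstriction engages before any plumage change
  vaso <- thermo_state(sp$k_flesh_min, 1, traits = sp, control = ctl)
  m_vaso <- vapply(ta_grid, function(ta)
    solve_heat_balance(sp, vaso, mild_hour(air = ta, sky = ta, ground = ta,
                                           active = TRUE),
                       ctl)$m_required_w, numeric(1))
  pick <- which(m_neutral > 1.05 * 2.5 * bmr &
                  abs(m_vaso - 2.5 * bmr) <= 0.05 * 2.5 * bmr)[1]
  expect_false(is.na(pick))
  res2 <- thermoregulate(sp, mild_hour(air = ta_grid[pick],
                                       sky = ta_grid[pick],
                                       ground = ta_grid[pick],
                                       active = TRUE), 2.5 * bmr, ctl)
  expect_equal(res2$state$k_flesh, sp$k_flesh_min)
  expect_equal(res2$state$plumage_depth_multiplier, 1)
  # idempotence: rerunning under identical conditions changes nothing
  res3 <- thermoregulate(sp, mild_hour(air = ta_grid[pick],
                                       sky = ta_grid[pick],
                                       ground = ta_grid[pick],
                                       active = TRUE), 2.5 * bmr, ctl)
  expect_identical(res2$state, res3$state)
  expect_identical(res2$m_required_w, res3$m_required_w)
})

test_that("heat stress engages wetting and shade, and can end in
           heat death", {
  sp <- parakeet()
  ctl <- tr_control()   # solar and evaporation on
  hot_sun <- mild_hour(air = 39, sky = 39, ground = 50, solar = 900,
                       rh = 30, wind = 1, active = TRUE)
  res <- thermoregulate(sp, hot_sun, 2.5 * sp$bmr_w, ctl)
  if (identical(res$status, "balanced") &&
      res$m_required_w < 0.95 * 2.5 * sp$bmr_w) {
    expect_true(res$state$in_shade)
    expect_equal(res$state$wet_skin_fraction, sp$wet_skin_max)
  }
  lethal <- mild_hour(air = 46, sky = 46, ground = 60, solar = 1000,
                      rh = 90, wind = 0.5, active = TRUE)
  res2 <- thermoregulate(sp, lethal, 2.5 * sp$bmr_w, ctl)
  expect_identical(res2$status, "heat_death")
  expect_lt(res2$m_required_w, sp$bmr_w)
  expect_true(res2$state$in_shade)
})
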