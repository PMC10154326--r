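# Shared fixtures. The "oracle" configuration is the setting under which
# the analytic truth map is exact: flat terrain, uniform land cover, zero
# diurnal range, solar and evaporation disabled, and a sea-level
# temperature placing the parakeet's cold edge mid-grid.

oracle_config <- function(seed = 1L, grid_rows = 20, grid_cols = 20, ...) {
  synthetic_config(grid_rows = grid_rows, grid_cols = grid_cols,
                   flat_terrain = TRUE, diurnal_range_c = 0,
                   sea_level_temp_c = 21.5,
                   landcover_probs = c(forest = 0, shrub_herb = 0,
                                       urban = 0, other = 1),
                   seed = seed, ...)
}

oracle_control <- function(...) {
  tr_control(solar_enabled = FALSE, evap_enabled = FALSE, ...)
}

parakeet <- local({
  sp <- NULL
  function() {
    if (is.null(sp)) sp <<- generate_species("medium_parakeet")
    sp
  }
})

# one cached oracle landscape + truth map, shared across tests
oracle_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      L <- generate_landscape(oracle_config(seed = 7))
      w <<- list(landscape = L,
                 truth = truth_suitability(parakeet(), L, oracle_control()))
    }
    w
  }
})

# a benign mid-latitude microclimate hour for solver tests
mild_hour <- function(air = 20, wind = 2, rh = 60, solar = 0,
                      sky = air - 15, ground = air, active = FALSE) {
  list(air_temp_c = air, wind_ms = wind, rh_pct = rh, solar_wm2 = solar,
       sky_temp_c = sky, ground_temp_c = ground,
       trad_c = 0.5 * (sky + ground), is_active = active)
}

# independent series-resistance closed form (test-side oracle): the
# required metabolic rate with solar and evaporation disabled
closed_form_m <- function(traits, state, mc, control) {
  hr <- 4 * control$emissivity * control$sigma *
    (control$lw_lin_temp_c + 273.15)^3
  tb <- traits$core_temp_c - control$core_skin_dt_c
  trad <- 0.5 * (mc$sky_temp_c + mc$ground_temp_c)
  q <- 0
  for (p in traits$parts) {
    hfree <- control$free_nu * control$k_air / p$d_char_m
    re <- mc$wind_ms * p$d_char_m / control$nu_air
    hc <- max(hfree, control$forced_nu_coef * control$k_air / p$d_char_m *
                re^control$wind_exponent)
    r <- p$flesh_depth_m / state$k_flesh
    if (isTRUE(p$has_fat) && traits$fat_fraction > 0)
      r <- r + traits$fat_fraction * 2 * p$flesh_depth_m / control$k_fat
    if (!p$bare) {
      depth <- (p$feather_depth_dorsal_m + p$feather_depth_ventral_m) / 2
      len <- (p$feather_length_dorsal_m + p$feather_length_ventral_m) / 2
      phi <- control$packing_coef * (traits$feather_diameter_m / depth) *
        (len / depth)
      phi <- min(control$packing_max, max(control$packing_min, phi))
      keff <- (1 - phi) * control$k_air_still + phi * control$k_keratin
      r <- r + depth * state$plumage_depth_multiplier / keff
    }
    te <- (hc * mc$air_temp_c + hr * trad) / (hc + hr)
    q <- q + p$area_eff_m2 * (tb - te) / (r + 1 / (hc + hr))
  }
  eta <- if (isTRUE(mc$is_active)) traits$muscle_efficiency else 0
  q / (1 - eta)
}

# random but physically plausible trait draw for property tests
random_traits <- function() {
  mass <- exp(stats::runif(1, log(0.008), log(1.2)))
  bird_traits(species = "random", mass_kg = mass,
              core_temp_c = stats::runif(1, 39, 43),
              bmr_w = 3.8 * mass^0.72 * stats::runif(1, 0.7, 1.3),
              fat_fraction = stats::runif(1, 0.02, 0.25),
              feather_depth_scale = stats::runif(1, 0.7, 1.3),
              feather_length_scale = stats::runif(1, 0.7, 1.3),
              animal_height_m = stats::runif(1, 0.1, 1.5))
}

random_state <- function(traits, control = tr_control()) {
  thermo_state(
    k_flesh = stats::runif(1, traits$k_flesh_min, traits$k_flesh_max),
    plumage_depth_multiplier = stats::runif(1, 1, control$ptiloerection_max),
    wet_skin_fraction = stats::runif(1, traits$wet_skin_min,
                                     traits$wet_skin_max),
    in_shade = stats::runif(1) < 0.3, traits = traits, control = control)
}

random_hour <- function() {
  air <- stats::runif(1, -30, 45)
  mild_hour(air = air, wind = stats::runif(1, 0, 10),
            rh = stats::runif(1, 5, 100),
            solar = stats::runif(1, 0, 1000) * (stats::runif(1) < 0.5),
            sky = air - stats::runif(1, 0, 25),
            ground = air + stats::runif(1, -2, 15),
            active = stats::runif(1) < 0.5)
}
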