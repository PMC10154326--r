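test_that("climate normals follow the configured gradients exactly", {
  cfg <- synthetic_config(grid_rows = 8, grid_cols = 6, flat_terrain = TRUE,
                          latitudinal_gradient_c_per_deg = 0.6,
                          lat_range = c(40, 50), seed = 2)
  cl <- generate_climate_normals(cfg)
  # 10 degrees of latitude at 0.6 C/deg: annual-mean tmax drops by 6.0 C
  mean_tmax <- apply(cl$tmax, 1, mean)
  expect_equal(mean_tmax[1] - mean_tmax[8], 6.0, tolerance = 1e-12)
  expect_true(all(cl$tmin <= cl$tmax))
  expect_equal(cl$tmax, cl$tmin + cfg$diurnal_range_c)
  # snow iff monthly tmax below freezing
  expect_equal(cl$snow, cl$tmax < 0)
})

test_that("degenerate gradients give a constant temperature field", {
  cfg <- synthetic_config(grid_rows = 5, grid_cols = 5, flat_terrain = TRUE,
                          seasonal_amplitude_c = 0,
                          latitudinal_gradient_c_per_deg = 0, seed = 1)
  cl <- generate_climate_normals(cfg)
  expect_equal(length(unique(as.vector(cl$tmin))), 1)
  expect_equal(length(unique(as.vector(cl$tmax))), 1)
})

test_that("seasonal cycle has exactly one annual maximum when forced", {
  cfg <- synthetic_config(grid_rows = 4, grid_cols = 4,
                          seasonal_amplitude_c = 7, flat_terrain = TRUE,
                          seed = 1)
  cl <- generate_climate_normals(cfg)
  series <- (cl$tmin[1, 1, ] + cl$tmax[1, 1, ]) / 2
  expect_equal(sum(series == max(series)), 1)
  expect_equal(which.max(series), 7)  # July in the northern hemisphere
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(grid_rows = 12, grid_cols = 10, seed = 9)
  expect_identical(generate_landscape(cfg), generate_landscape(cfg))
  expect_identical(generate_terrain(cfg), generate_terrain(cfg))
  tm <- oracle_world()$truth
  occ1 <- sample_occurrences(tm, oracle_world()$landscape, 25, 0.5, seed = 4)
  occ2 <- sample_occurrences(tm, oracle_world()$landscape, 25, 0.5, seed = 4)
  expect_identical(occ1, occ2)
})

test_that("terrain respects its declared ranges and class rules", {
  cfg <- synthetic_config(grid_rows = 100, grid_cols = 100, seed = 21)
  tr <- generate_terrain(cfg)
  expect_true(all(tr$elevation >= 0))
  expect_true(all(tr$slope >= 0 & tr$slope <= 60))
  expect_true(all(tr$aspect >= 0 & tr$aspect < 360))
  expect_true(all(tr$landcover %in% c("forest", "shrub_herb", "urban",
                                      "other")))
  expect_true(all(tr$soil %in% c("sand", "rock", "soil", "concrete")))
  expect_true(all(tr$soil[tr$landcover == "urban"] == "concrete"))
  # urban fraction within 2 percentage points of the configured mixture
  expect_lt(abs(mean(tr$landcover == "urban") - 0.1), 0.02)
  flat <- generate_terrain(synthetic_config(grid_rows = 5, grid_cols = 5,
                                            flat_terrain = TRUE, seed = 1))
  expect_true(all(flat$slope == 0) && all(flat$aspect == 0))
})

test_that("species archetypes carry their documented masses and density", {
  expect_equal(generate_species("medium_parakeet")$mass_kg, 0.170)
  expect_equal(generate_species("small_finch")$mass_kg, 0.009)
  expect_equal(generate_species("large_pheasant")$mass_kg, 1.0)
  for (a in c("small_finch", "medium_parakeet", "large_pheasant")) {
    sp <- generate_species(a)
    expect_equal(sp$body_density_kg_m3, 875)
    expect_gt(sp$bmr_w, 0)
    expect_true(all(vapply(sp$parts, function(p) p$area_m2 > 0, logical(1))))
  }
  expect_error(generate_species("unknown_bird"))
})

test_that("truth map matches an independent brute-force closed form", {
  w <- oracle_world()
  L <- w$landscape; tm <- w$truth
  sp <- parakeet(); ctl <- oracle_control()
  hr <- 4 * ctl$emissivity * ctl$sigma * (ctl$lw_lin_temp_c + 273.15)^3
  nr <- L$grid_rows; nc <- L$grid_cols
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    m <- which.min(L$tmin[r, cc, ])
    ta <- L$tmin[r, cc, m]
    tsky <- sky_temperature(ta, L$cloud[r, cc, m], ctl)
    tgnd <- ground_temperature(ta, 0, L$snow[r, cc, m], ctl)
    mc <- list(air_temp_c = ta, sky_temp_c = tsky, ground_temp_c = tgnd,
               wind_ms = wind_at_height(L$wind[r, cc, m], "other",
                                        sp$animal_height_m, ctl),
               is_active = FALSE)
    state <- thermo_state(sp$k_flesh_min, ctl$ptiloerection_max,
                          sp$wet_skin_min, FALSE, sp, ctl)
    q <- closed_form_m(sp, state, mc, ctl)
    nact <- sum(solar_geometry(L$lat[r], 0, month_doy(m),
                               0:23)$zenith_deg <= ctl$active_zenith_deg)
    f <- nact / 24
    m_req <- q * (f / (1 - sp$muscle_efficiency) + (1 - f))
    expect_equal(tm$m_required_w[r, cc], m_req, tolerance = 1e-9)
    expect_identical(tm$at_risk[r, cc],
                     m_req <= sp$intake_ceiling_multiplier * sp$bmr_w)
  }
})

test_that("truth map boundary cases behave as the closed form dictates", {
  w <- oracle_world()
  sp <- parakeet()
  # warming everything to just below Tb: every cell becomes at risk
  warm <- w$landscape
  shift <- sp$core_temp_c - 1 - max(warm$tmax)
  warm$tmin <- warm$tmin + shift
  warm$tmax <- warm$tmax + shift
  warm$snow <- warm$tmax < 0
  expect_true(all(warm$tmin < sp$core_temp_c))
  expect_true(all(truth_suitability(sp, warm, oracle_control())$at_risk))
  # cells colder than the critical isotherm are not at risk (flat world:
  # constant wind makes the isotherm exact)
  tm <- w$truth
  tmin_min <- apply(w$landscape$tmin, c(1, 2), min)
  expect_true(all(!tm$at_risk[tmin_min < tm$critical_isotherm_c - 1e-9]))
  expect_true(all(tm$at_risk[tmin_min > tm$critical_isotherm_c + 1e-9]))
})

test_that("occurrence sampling honours the truth map and the bias switch", {
  w <- oracle_world()
  occ <- sample_occurrences(w$truth, w$landscape, 500, 0, seed = 3)
  cells <- attr(occ, "cell")
  expect_true(all(w$truth$at_risk[cells]))
  expect_equal(nrow(sample_occurrences(w$truth, w$landscape, 0, 0, 1)), 0)
  # unbiased sampling is uniform over at-risk cells (chi-square, n = 10000)
  occ2 <- sample_occurrences(w$truth, w$landscape, 10000, 0, seed = 5)
  tab <- table(factor(attr(occ2, "cell"),
                      levels = which(w$truth$at_risk)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
  # no suitable cells: error
  none <- w$truth; none$at_risk[] <- FALSE
  expect_error(sample_occurrences(none, w$landscape, 5, 0, 1),
               "insufficient")
})

test_that("landscape, occurrence and trait writers round-trip to CSV", {
  tmp <- withr::local_tempdir()
  w <- oracle_world()
  p1 <- write_landscape_csv(w$landscape, file.path(tmp, "land.csv"))
  df <- utils::read.csv(p1)
  expect_equal(nrow(df), w$landscape$grid_rows * w$landscape$grid_cols)
  expect_true(all(sprintf("tmin_m%02d", 1:12) %in% names(df)))
  occ <- sample_occurrences(w$truth, w$landscape, 10, 0, 1)
  p2 <- write_occurrences_csv(occ, file.path(tmp, "occ.csv"))
  expect_equal(names(utils::read.csv(p2)),
               c("species", "lon", "lat", "range"))
  p3 <- write_traits_csv(parakeet(), file.path(tmp, "traits.csv"))
  tdf <- utils::read.csv(p3)
  expect_equal(sum(tdf$record == "species"), 1)
  expect_equal(sum(tdf$record == "part"), length(parakeet()$parts))
})
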