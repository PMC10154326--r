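#' Configuration of the synthetic landscape generators
#'
#' Bundles and validates the parameters of the seeded landscape, climate
#' and occurrence generators. Defaults describe a northern-hemisphere,
#' subtropical-to-temperate gradient (month 1 = January = winter) on which
#' the cold edges of all three packaged species archetypes fall inside the
#' grid.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 2). Rows run south to
#'   north.
#' @param lat_range,lon_range extent in decimal degrees.
#' @param sea_level_temp_c annual-mean air temperature at sea level at the
#'   southern border (C).
#' @param lapse_rate_c_per_km temperature lapse rate with elevation (C/km).
#' @param latitudinal_gradient_c_per_deg cooling per degree of latitude
#'   northwards (C/deg).
#' @param seasonal_amplitude_c half-amplitude of the seasonal sinusoid (C);
#'   the warmest month is July.
#' @param diurnal_range_c daily temperature range, `tmax - tmin` (C, >= 0).
#' @param mean_wind_ms reference wind speed at 2 m (m/s); spatially and
#'   seasonally constant, as in monthly-normal products without wind
#'   extremes.
#' @param cloud_mean_frac cloud fraction in `[0, 1]`, constant.
#' @param relief_amplitude_m peak-to-trough elevation of the smoothed
#'   random topography (m); ignored when `flat_terrain`.
#' @param smoothing_cells half-width of the moving-average kernel giving
#'   the terrain its spatial autocorrelation (cells).
#' @param landcover_probs named mixture over the classes `forest`,
#'   `shrub_herb`, `urban`, `other`.
#' @param flat_terrain logical; if TRUE elevation, slope and aspect are 0.
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 60, grid_cols = 60,
                             lat_range = c(35, 65), lon_range = c(-10, 30),
                             sea_level_temp_c = 26,
                             lapse_rate_c_per_km = 6.5,
                             latitudinal_gradient_c_per_deg = 0.6,
                             seasonal_amplitude_c = 6,
                             diurnal_range_c = 8,
                             mean_wind_ms = 3,
                             cloud_mean_frac = 0.5,
                             relief_amplitude_m = 600,
                             smoothing_cells = 3,
                             landcover_probs = c(forest = 0.3,
                                                 shrub_herb = 0.4,
                                                 urban = 0.1, other = 0.2),
                             flat_terrain = FALSE,
                             seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              lat_range = lat_range, lon_range = lon_range,
              sea_level_temp_c = sea_level_temp_c,
              lapse_rate_c_per_km = lapse_rate_c_per_km,
              latitudinal_gradient_c_per_deg = latitudinal_gradient_c_per_deg,
              seasonal_amplitude_c = seasonal_amplitude_c,
              diurnal_range_c = diurnal_range_c,
              mean_wind_ms = mean_wind_ms,
              cloud_mean_frac = cloud_mean_frac,
              relief_amplitude_m = relief_amplitude_m,
              smoothing_cells = as.integer(smoothing_cells),
              landcover_probs = landcover_probs,
              flat_terrain = isTRUE(flat_terrain),
              seed = as.integer(seed))
  num <- unlist(cfg[c("lat_range", "lon_range", "sea_level_temp_c",
                      "lapse_rate_c_per_km", "latitudinal_gradient_c_per_deg",
                      "seasonal_amplitude_c", "diurnal_range_c",
                      "mean_wind_ms", "cloud_mean_frac",
                      "relief_amplitude_m")])
  stopifnot_finite(num, "config values")
  if (cfg$grid_rows < 2 || cfg$grid_cols < 2)
    stop("grid dimensions must be >= 2")
  if (cfg$diurnal_range_c < 0) stop("diurnal_range_c must be >= 0")
  if (cfg$cloud_mean_frac < 0 || cfg$cloud_mean_frac > 1)
    stop("cloud_mean_frac must be in [0,1]")
  if (abs(sum(landcover_probs) - 1) > 1e-8)
    stop("landcover_probs must sum to 1")
  class(cfg) <- "synthetic_config"
  cfg
}

# evaluate an expression under a given seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# moving-average smoothing of a matrix with replicate padding
smooth_matrix <- function(m, w) {
  if (w < 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x, n) x[pmin(pmax(seq_len(n + 2 * w) - w, 1), n)]
  mp <- m[pad(seq_len(nr), nr), pad(seq_len(nc), nc)]
  k <- 2 * w + 1
  cs <- apply(mp, 2, function(col) {
    c0 <- cumsum(col)
    (c0[k:length(col)] - c(0, c0[seq_len(length(col) - k)])) / k
  })
  cs <- t(apply(cs, 1, function(row) {
    c0 <- cumsum(row)
    (c0[k:length(row)] - c(0, c0[seq_len(length(row) - k)])) / k
  }))
  cs
}

#' Generate gridded monthly climate normals
#'
#' Monthly mean temperature is a deterministic function of latitude,
#' elevation and month: the sea-level southern-border mean, minus the
#' latitudinal gradient, minus the lapse-rate elevation correction, plus a
#' seasonal cosine peaking in July. `tmin` and `tmax` straddle the mean by
#' half the diurnal range, wind and cloud are the configured constants, and
#' snow is flagged wherever the monthly `tmax` is below 0 C.
#'
#' @param cfg a [synthetic_config()].
#' @param terrain optional terrain from [generate_terrain()]; if missing,
#'   elevation 0 is assumed.
#' @return A list with `lat`, `lon` axis vectors and `[row, col, month]`
#'   arrays `tmin`, `tmax`, `wind`, `cloud`, `snow`.
#' @export
generate_climate_normals <- function(cfg, terrain = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = nr)
  lon <- seq(cfg$lon_range[1], cfg$lon_range[2], length.out = nc)
  elev <- if (is.null(terrain)) matrix(0, nr, nc) else terrain$elevation
  tmean_base <- cfg$sea_level_temp_c -
    cfg$latitudinal_gradient_c_per_deg * (lat - cfg$lat_range[1])
  tmin <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) {
    seasonal <- cfg$seasonal_amplitude_c * cos(2 * pi * (m - 7) / 12)
    tmean <- matrix(tmean_base, nr, nc) -
      cfg$lapse_rate_c_per_km * elev / 1000 + seasonal
    tmin[, , m] <- tmean - cfg$diurnal_range_c / 2
  }
  tmax <- tmin + cfg$diurnal_range_c
  list(lat = lat, lon = lon, tmin = tmin, tmax = tmax,
       wind = array(cfg$mean_wind_ms, c(nr, nc, 12)),
       cloud = array(cfg$cloud_mean_frac, c(nr, nc, 12)),
       snow = tmax < 0)
}

#' Generate spatially autocorrelated synthetic terrain
#'
#' Elevation is smoothed seeded Gaussian noise rescaled to
#' `[0, relief_amplitude_m]`; slope and aspect derive from its finite
#' differences (slope capped at 60 degrees); land cover is drawn per cell
#' from the configured mixture, and soil class is sampled from
#' sand/rock/soil except that urban cells are always concrete.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with matrices `elevation`, `slope`, `aspect`,
#'   `landcover`, `soil` and the flag `flat_terrain`.
#' @export
generate_terrain <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  with_seed(cfg$seed, {
    if (cfg$flat_terrain) {
      elev <- matrix(0, nr, nc)
      slope <- matrix(0, nr, nc)
      aspect <- matrix(0, nr, nc)
    } else {
      z <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                         cfg$smoothing_cells)
      rng <- range(z)
      elev <- cfg$relief_amplitude_m * (z - rng[1]) / max(diff(rng), 1e-12)
      dlat <- diff(cfg$lat_range) / max(nr - 1, 1)
      dlon <- diff(cfg$lon_range) / max(nc - 1, 1)
      midlat <- mean(cfg$lat_range) * pi / 180
      dy <- 111320 * dlat
      dx <- 111320 * dlon * cos(midlat)
      gy <- (elev[pmin(seq_len(nr) + 1, nr), ] -
               elev[pmax(seq_len(nr) - 1, 1), ]) / (2 * dy)
      gx <- (elev[, pmin(seq_len(nc) + 1, nc)] -
               elev[, pmax(seq_len(nc) - 1, 1)]) / (2 * dx)
      slope <- pmin(atan(sqrt(gx^2 + gy^2)) * 180 / pi, 60)
      aspect <- (atan2(-gx, gy) * 180 / pi) %% 360
    }
    lc <- matrix(sample(names(cfg$landcover_probs), nr * nc, replace = TRUE,
                        prob = cfg$landcover_probs), nr, nc)
    soil <- matrix(sample(c("sand", "rock", "soil"), nr * nc, replace = TRUE),
                   nr, nc)
    soil[lc == "urban"] <- "concrete"
    list(elevation = elev, slope = slope, aspect = aspect,
         landcover = lc, soil = soil, flat_terrain = cfg$flat_terrain)
  })
}

#' Thermal and radiative properties of the generalized soil classes
#'
#' @param soil_class character vector of classes among `sand`, `rock`,
#'   `soil`, `concrete`.
#' @return A data.frame with `conductivity_w_mk`, `density_kg_m3`,
#'   `specific_heat_j_kgk`, `reflectivity` per input class.
#' @export
resolve_soil_properties <- function(soil_class) {
  tab <- data.frame(
    soil_class = c("sand", "rock", "soil", "concrete"),
    conductivity_w_mk = c(0.30, 2.90, 0.80, 1.70),
    density_kg_m3 = c(1600, 2700, 1400, 2300),
    specific_heat_j_kgk = c(800, 790, 1100, 880),
    reflectivity = c(0.35, 0.25, 0.15, 0.30)
  )
  i <- match(soil_class, tab$soil_class)
  if (anyNA(i)) stop("unknown soil class")
  tab[i, , drop = FALSE]
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper composing [generate_terrain()] and
#' [generate_climate_normals()] into the single landscape object consumed
#' by the microclimate and suitability stages.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `tr_landscape` holding the grid axes, monthly
#'   climate arrays and terrain matrices.
#' @export
generate_landscape <- function(cfg) {
  terrain <- generate_terrain(cfg)
  climate <- generate_climate_normals(cfg, terrain)
  out <- c(list(grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols,
                config = cfg),
           climate, terrain)
  class(out) <- "tr_landscape"
  out
}

#' @export
print.tr_landscape <- function(x, ...) {
  cat("synthetic landscape:", x$grid_rows, "x", x$grid_cols, "cells,",
      "lat", paste(round(range(x$lat), 2), collapse = ".."),
      "lon", paste(round(range(x$lon), 2), collapse = ".."), "\n")
  cat("  January tmin range:",
      paste(round(range(x$tmin[, , 1]), 1), collapse = " .. "), "C\n")
  invisible(x)
}

#' Generate a bird species archetype
#'
#' Returns a full trait set for one of three archetypes spanning the body
#' sizes of the modelled invaders: a ~9 g estrildid finch, a ~170 g
#' parakeet and a ~1 kg pheasant. Geometry is derived from mass at the
#' default body density of 875 kg/m3, basal metabolic rate follows the
#' allometry `3.8 * mass_kg^0.72` W, and feather depths and lengths scale
#' isometrically (mass^(1/3)) from the parakeet reference plumage.
#'
#' @param archetype one of `"small_finch"`, `"medium_parakeet"`,
#'   `"large_pheasant"`.
#' @param seed integer seed recorded in the traits (the archetypes
#'   themselves are deterministic).
#' @return A `bird_traits` list; see [bird_traits()].
#' @export
#' @examples
#' sp <- generate_species("medium_parakeet")
#' sp$mass_kg  # 0.170
generate_species <- function(archetype = c("small_finch", "medium_parakeet",
                                           "large_pheasant"), seed = 1L) {
  archetype <- match.arg(archetype)
  spec <- switch(archetype,
    small_finch = list(mass = 0.009, tb = 41.5, height = 1.20, breed = 2L),
    medium_parakeet = list(mass = 0.170, tb = 41.0, height = 1.50,
                           breed = 3L),
    large_pheasant = list(mass = 1.000, tb = 41.0, height = 0.20, breed = 3L)
  )
  bird_traits(species = archetype, mass_kg = spec$mass,
              core_temp_c = spec$tb,
              bmr_w = 3.8 * spec$mass^0.72,
              breeding_duration_months = spec$breed,
              animal_height_m = spec$height,
              seed = as.integer(seed))
}

#' Analytic truth map of energetic suitability
#'
#' Closed-form oracle classifying each cell as invadable (`at_risk`) from
#' the coldest-month minimum temperature alone: the bird is held at its
#' cold-extreme thermoregulatory state (full vasoconstriction, maximum
#' ptiloerection), solar gain and evaporation are excluded, and the
#' required metabolic rate is
#' `M = sum_p G_p * (Tb - Te_p) * w_act`, where `G_p` is each body part's
#' series conductance, `Te_p` the part's operative temperature built from
#' the coldest-month `tmin` and the documented sky/ground longwave
#' temperatures, and `w_act` the activity-weighted work-export factor. The
#' cell is at risk iff `M <= intake_ceiling_multiplier * BMR`. The
#' effective whole-body resistance `R_total = (Tb - tmin) / M` is reported
#' alongside the map.
#'
#' This is deliberately not a run of the hourly model: there is no
#' thermoregulatory cascade, no diurnal course and no solver; under the
#' oracle preconditions (flat terrain, zero diurnal range, solar and
#' evaporation disabled) the hourly model must reproduce its cold edge.
#'
#' @param traits a `bird_traits` object.
#' @param climate a climate-normals list (or full landscape).
#' @param control a [tr_control()] list; solar/evaporation switches are
#'   forced off inside the oracle.
#' @return A list of class `truth_map`: logical matrix `at_risk`,
#'   `critical_isotherm_c` (coldest-month tmin at which `M` equals the
#'   intake ceiling, for the grid-mean wind), matrix `r_total`, and a
#'   `provenance` string stating the closed form.
#' @export
truth_suitability <- function(traits, climate, control = tr_control()) {
  control$solar_enabled <- FALSE
  control$evap_enabled <- FALSE
  nr <- dim(climate$tmin)[1]; nc <- dim(climate$tmin)[2]
  lat <- climate$lat
  # coldest month per cell by tmin
  tmin_min <- apply(climate$tmin, c(1, 2), min)
  cold_month <- apply(climate$tmin, c(1, 2), which.min)
  state <- thermo_state(k_flesh = traits$k_flesh_min,
                        plumage_depth_multiplier = control$ptiloerection_max,
                        wet_skin_fraction = traits$wet_skin_min,
                        in_shade = FALSE, traits = traits,
                        control = control)
  hr <- radiative_coefficient(control)
  m_req <- matrix(NA_real_, nr, nc)
  w_act_row <- matrix(NA_real_, nr, 12)
  for (m in 1:12) {
    zen <- vapply(lat, function(la)
      sum(solar_geometry(la, 0, month_doy(m), 0:23)$zenith_deg <=
            control$active_zenith_deg), numeric(1))
    f_act <- zen / 24
    w_act_row[, m] <- f_act / (1 - traits$muscle_efficiency) + (1 - f_act)
  }
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    m <- cold_month[r, cc]
    ta <- climate$tmin[r, cc, m]
    cloud <- climate$cloud[r, cc, m]
    snow <- climate$snow[r, cc, m]
    tsky <- sky_temperature(ta, cloud, control)
    tgnd <- ground_temperature(ta, 0, snow, control)
    trad <- 0.5 * (tsky + tgnd)
    v <- wind_at_height(climate$wind[r, cc, m], "other",
                        traits$animal_height_m, control)
    q <- 0
    for (p in traits$parts) {
      hc <- convective_coefficient(v, p$d_char_m, ta, control)
      hx <- hc + hr
      rins <- insulation_resistance(p, state, state$k_flesh, traits, control)
      te <- (hc * ta + hr * trad) / hx
      q <- q + p$area_eff_m2 * (traits$core_temp_c - te) / (rins + 1 / hx)
    }
    m_req[r, cc] <- q * w_act_row[r, m]
  }
  ceiling_w <- traits$intake_ceiling_multiplier * traits$bmr_w
  at_risk <- m_req <= ceiling_w
  r_total <- (traits$core_temp_c - tmin_min) / pmax(m_req, 1e-12)
  # isotherm from the grid-mean conditions: tmin at which M equals ceiling
  mean_ratio <- mean((traits$core_temp_c - tmin_min) / pmax(m_req, 1e-12))
  critical <- traits$core_temp_c - ceiling_w * mean_ratio
  structure(list(at_risk = at_risk, critical_isotherm_c = critical,
                 r_total = r_total, m_required_w = m_req,
                 provenance = paste(
                   "closed form: M = sum_p A_p (Tb - Te_p)/(R_p + 1/h_p)",
                   "* w_act at coldest-month tmin, cold-extreme state,",
                   "no solar, no evaporation; at_risk iff M <= 4.6 BMR")),
            class = "truth_map")
}

#' Sample presence-only occurrences from a truth map
#'
#' Draws `n` presence points from the at-risk cells of a truth map, with an
#' optional accessibility bias: with `bias_strength > 0` a cell's sampling
#' weight decays as `exp(-bias_strength * d / 10)` with `d` the Chebyshev
#' distance (in cells) to the nearest urban cell. Points are jittered
#' uniformly within their cell.
#'
#' @param truth a `truth_map`.
#' @param landscape the landscape the truth map was computed on (supplies
#'   the lat/lon axes and urban cells).
#' @param n number of points (>= 0).
#' @param bias_strength accessibility bias in `[0, 1]`.
#' @param seed integer seed.
#' @param range_label `"native"` or `"invasive"` label for the output.
#' @param species species name for the output.
#' @return A data.frame `species, lon, lat, range` with attribute
#'   `cell` (sampled cell indices).
#' @export
sample_occurrences <- function(truth, landscape, n, bias_strength = 0,
                               seed = 1L, range_label = "invasive",
                               species = "species") {
  cells <- which(truth$at_risk)
  if (n > 0 && length(cells) == 0) stop("insufficient suitable cells")
  if (n == 0) {
    out <- data.frame(species = character(), lon = numeric(),
                      lat = numeric(), range = character())
    attr(out, "cell") <- integer(0)
    return(out)
  }
  nr <- nrow(truth$at_risk); nc <- ncol(truth$at_risk)
  w <- rep(1, length(cells))
  if (bias_strength > 0) {
    urb <- which(landscape$landcover == "urban")
    if (length(urb)) {
      ur <- (urb - 1L) %% nr + 1L; uc <- (urb - 1L) %/% nr + 1L
      cr <- (cells - 1L) %% nr + 1L; ccol <- (cells - 1L) %/% nr + 1L
      d <- vapply(seq_along(cells), function(i)
        min(pmax(abs(cr[i] - ur), abs(ccol[i] - uc))), numeric(1))
      w <- exp(-bias_strength * d / 10)
    }
  }
  with_seed(seed, {
    idx <- sample(cells, n, replace = TRUE, prob = w)
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    dlat <- if (length(landscape$lat) > 1) diff(landscape$lat[1:2]) else 0
    dlon <- if (length(landscape$lon) > 1) diff(landscape$lon[1:2]) else 0
    out <- data.frame(
      species = species,
      lon = landscape$lon[cc] + stats::runif(n, -0.5, 0.5) * dlon,
      lat = landscape$lat[r] + stats::runif(n, -0.5, 0.5) * dlat,
      range = range_label
    )
    attr(out, "cell") <- idx
    out
  })
}

#' Map occurrence points to landscape cell indices
#'
#' @param occurrences a data.frame with `lon`, `lat`.
#' @param landscape a `tr_landscape`.
#' @return Integer vector of cell indices (column-major, row fastest).
#' @export
occurrence_cells <- function(occurrences, landscape) {
  nr <- landscape$grid_rows
  r <- vapply(occurrences$lat, function(y)
    which.min(abs(landscape$lat - y)), integer(1))
  cc <- vapply(occurrences$lon, function(x)
    which.min(abs(landscape$lon - x)), integer(1))
  (cc - 1L) * nr + r
}

#' Write climate normals and terrain as long-format CSV
#'
#' One row per cell; monthly variables appear as `<var>_m01` .. `<var>_m12`
#' column bands (documented band order: months 1-12 per variable).
#'
#' @param landscape a `tr_landscape`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  nr <- landscape$grid_rows; nc <- landscape$grid_cols
  cell <- seq_len(nr * nc)
  r <- (cell - 1L) %% nr + 1L; cc <- (cell - 1L) %/% nr + 1L
  df <- data.frame(cell = cell, row = r, col = cc,
                   lat = landscape$lat[r], lon = landscape$lon[cc],
                   elevation_m = as.vector(landscape$elevation),
                   slope_deg = as.vector(landscape$slope),
                   aspect_deg = as.vector(landscape$aspect),
                   landcover = as.vector(landscape$landcover),
                   soil = as.vector(landscape$soil))
  for (v in c("tmin", "tmax", "wind", "cloud", "snow")) {
    arr <- landscape[[v]]
    for (m in 1:12) df[[sprintf("%s_m%02d", v, m)]] <- as.vector(arr[, , m])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write occurrences as CSV (`species,lon,lat,range`)
#' @param occurrences occurrence data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_occurrences_csv <- function(occurrences, path) {
  utils::write.csv(occurrences[, c("species", "lon", "lat", "range")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a trait set as CSV, one row per body part plus a species row
#' @param traits a `bird_traits`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  sp <- data.frame(
    record = "species", part = NA, species = traits$species,
    mass_kg = traits$mass_kg, body_density_kg_m3 = traits$body_density_kg_m3,
    fat_fraction = traits$fat_fraction, core_temp_c = traits$core_temp_c,
    bmr_w = traits$bmr_w, animal_height_m = traits$animal_height_m,
    breeding_duration_months = traits$breeding_duration_months,
    area_m2 = NA, feather_depth_dorsal_m = NA, feather_depth_ventral_m = NA,
    feather_length_dorsal_m = NA, feather_length_ventral_m = NA,
    refl_dorsal = NA, refl_ventral = NA, bare = NA
  )
  parts <- do.call(rbind, lapply(traits$parts, function(p) data.frame(
    record = "part", part = p$name, species = traits$species,
    mass_kg = NA, body_density_kg_m3 = NA, fat_fraction = NA,
    core_temp_c = NA, bmr_w = NA, animal_height_m = NA,
    breeding_duration_months = NA,
    area_m2 = p$area_m2,
    feather_depth_dorsal_m = p$feather_depth_dorsal_m,
    feather_depth_ventral_m = p$feather_depth_ventral_m,
    feather_length_dorsal_m = p$feather_length_dorsal_m,
    feather_length_ventral_m = p$feather_length_ventral_m,
    refl_dorsal = p$refl_dorsal, refl_ventral = p$refl_ventral,
    bare = p$bare
  )))
  utils::write.csv(rbind(sp, parts), path, row.names = FALSE)
  invisible(path)
}
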