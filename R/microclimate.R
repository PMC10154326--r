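#' Solar position, sunrise and sunset
#'
#' Standard solar-position geometry for a given site and hour (local solar
#' time). Declination follows the Cooper relation; the hour angle is
#' \code{15 * (hour - 12)} degrees.
#'
#' @param lat,lon latitude and longitude in decimal degrees (WGS84). The
#'   longitude is accepted for interface completeness; hours are local solar
#'   time, so the position depends on latitude, day and hour only.
#' @param day_of_year integer day of year (1-366).
#' @param hour hour of day in \code{[0, 24)}, local solar time. Vectorized.
#' @return A list with `zenith_deg`, `azimuth_deg` (clockwise from north),
#'   `sunrise_h`, `sunset_h`. Under polar night sunrise and sunset are both
#'   12 (zero-length day sentinel); under polar day they are 0 and 24.
#' @export
#' @examples
#' solar_geometry(0, 0, 80, 12)$zenith_deg  # near 0 at an equinox noon
solar_geometry <- function(lat, lon, day_of_year, hour) {
  if (abs(lat) > 90) stop("latitude out of range")
  decl <- 23.45 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- lat * pi / 180
  del <- decl * pi / 180
  h_ang <- (hour - 12) * 15 * pi / 180
  cosz <- sin(phi) * sin(del) + cos(phi) * cos(del) * cos(h_ang)
  cosz <- pmin(1, pmax(-1, cosz))
  zen <- acos(cosz) * 180 / pi
  sinz <- sin(acos(cosz))
  cosaz <- ifelse(sinz < 1e-9, 1,
                  (sin(del) - sin(phi) * cosz) / (cos(phi) * sinz))
  cosaz <- pmin(1, pmax(-1, cosaz))
  az <- acos(cosaz) * 180 / pi
  az <- ifelse(h_ang > 0, 360 - az, az)

  cos_h0 <- -tan(phi) * tan(del)
  if (cos_h0 > 1) {          # sun never rises
    sunrise <- 12; sunset <- 12
  } else if (cos_h0 < -1) {  # sun never sets
    sunrise <- 0; sunset <- 24
  } else {
    h0 <- acos(cos_h0) * 180 / pi / 15
    sunrise <- 12 - h0
    sunset <- 12 + h0
  }
  list(zenith_deg = zen, azimuth_deg = az,
       sunrise_h = sunrise, sunset_h = sunset)
}

#' Hourly air temperature from monthly extremes
#'
#' Sinusoidal diurnal course anchored at the monthly-normal extremes: the
#' minimum is reached at sunrise and the maximum at solar noon + 2 h
#' (hour 14 in solar time); the night branch is the symmetric cosine
#' decaying from the afternoon peak back to the next sunrise.
#'
#' @param tmin_c,tmax_c monthly-normal daily minimum and maximum air
#'   temperature (C); `tmin_c <= tmax_c`.
#' @param hour hour of day (vectorized), local solar time.
#' @param sunrise_h sunrise hour; degenerate values (polar sentinels, or
#'   later than the warm peak) fall back to 6 h.
#' @return Air temperature (C), always within `[tmin_c, tmax_c]`.
#' @export
hourly_air_temperature <- function(tmin_c, tmax_c, hour, sunrise_h = 6) {
  if (any(tmin_c > tmax_c)) stop("tmin must not exceed tmax")
  peak_h <- 14
  tr <- sunrise_h
  if (!is.finite(tr) || tr <= 0 || tr >= peak_h - 0.5) tr <- 6
  amp <- (tmax_c - tmin_c) / 2
  mid <- (tmax_c + tmin_c) / 2
  h <- hour %% 24
  day <- h >= tr & h <= peak_h
  out <- numeric(length(h))
  # rising branch: half cosine from tmin at sunrise to tmax at the peak
  out[day] <- mid - amp * cos(pi * (h[day] - tr) / (peak_h - tr))
  # night branch: half cosine from tmax at the peak to tmin at next sunrise
  hn <- ifelse(h < tr, h + 24, h)
  night <- !day
  out[night] <- mid + amp * cos(pi * (hn[night] - peak_h) / (tr + 24 - peak_h))
  out
}

#' Clear-sky and cloud-adjusted solar flux on an inclined surface
#'
#' Beam flux follows a broadband transmittance model,
#' \code{S0 * tau^m} with the Kasten-Young optical air mass, projected on
#' the slope/aspect-defined surface; the diffuse term is
#' \code{0.3 * S0 * (1 - tau^m) * cos(zenith)}. Cloud attenuates the total
#' linearly down to the overcast transmission floor.
#'
#' @param zenith_deg solar zenith angle (deg); flux is 0 at or beyond 90.
#' @param slope_deg,aspect_deg surface slope and aspect (deg, aspect
#'   clockwise from north).
#' @param azimuth_deg solar azimuth (deg).
#' @param cloud_frac cloud fraction in `[0, 1]`.
#' @param control a [tr_control()] list.
#' @return Global solar flux on the surface (W/m2), >= 0.
#' @export
incident_solar <- function(zenith_deg, slope_deg = 0, aspect_deg = 0,
                           azimuth_deg = 180, cloud_frac = 0,
                           control = tr_control()) {
  if (any(zenith_deg < 0 | zenith_deg > 180)) stop("zenith out of [0,180]")
  s0 <- control$solar_constant_wm2
  tau <- control$atm_transmittance
  z <- zenith_deg
  up <- z < 90
  cosz <- cos(z * pi / 180)
  m <- 1 / (cosz + 0.50572 * (96.07995 - z)^-1.6364)
  tm <- ifelse(up, tau^m, 0)
  beam_normal <- s0 * tm
  sr <- slope_deg * pi / 180
  cosi <- cosz * cos(sr) +
    sin(z * pi / 180) * sin(sr) * cos((azimuth_deg - aspect_deg) * pi / 180)
  direct <- beam_normal * pmax(cosi, 0)
  diffuse <- control$diffuse_fraction * s0 * (1 - tm) * pmax(cosz, 0)
  clear <- ifelse(up, direct + diffuse, 0)
  cloudf <- 1 - (1 - control$overcast_transmission) * cloud_frac
  pmax(clear * cloudf, 0)
}

#' Wind speed at animal height
#'
#' The 2 m reference wind is first scaled by the land-cover shelter factor
#' (forest 0.50, shrub/herbaceous 0.90, urban 0.75, other 1.00) and then
#' moved to animal height along a neutral logarithmic profile with
#' roughness length 0.01 m.
#'
#' @param ref_wind_ms reference wind speed at 2 m (m/s, >= 0).
#' @param landcover one of `"forest"`, `"shrub_herb"`, `"urban"`, `"other"`.
#' @param animal_height_m height of the animal above ground (m).
#' @param control a [tr_control()] list.
#' @return Wind speed at animal height (m/s).
#' @export
#' @examples
#' wind_at_height(4, "forest", 2)  # 2.0: the forest factor alone
wind_at_height <- function(ref_wind_ms, landcover = "other",
                           animal_height_m = 1, control = tr_control()) {
  if (any(ref_wind_ms < 0)) stop("wind must be non-negative")
  fac <- c(forest = 0.50, shrub_herb = 0.90, urban = 0.75, other = 1.00)
  if (any(!landcover %in% names(fac))) stop("unknown landcover class")
  z0 <- control$roughness_length_m
  h <- pmax(animal_height_m, control$min_height_m)
  prof <- log(h / z0) / log(control$reference_height_m / z0)
  pmax(ref_wind_ms * unname(fac[landcover]) * prof, 0)
}

#' Hourly relative humidity under constant water mass
#'
#' Vapor pressure is pinned at saturation at the daily minimum temperature
#' (so humidity peaks at 100% at that hour) and held constant over the day;
#' RH at other hours follows from the saturation pressure at the current
#' temperature, capped at 100%.
#'
#' @param hourly_temps_c vector of air temperatures (C).
#' @param tmin_c daily minimum temperature (C).
#' @return Relative humidity (%) for each hour, in `[0, 100]`.
#' @export
hourly_humidity <- function(hourly_temps_c, tmin_c) {
  stopifnot_finite(hourly_temps_c, "temperatures")
  pmin(100, 100 * e_sat_kpa(tmin_c) / e_sat_kpa(hourly_temps_c))
}

#' Effective sky temperature from a clear/overcast emissivity blend
#'
#' `eps_sky = (1 - cloud) * eps_clear(Ta) + cloud`, with the clear-sky
#' emissivity increasing weakly with air temperature; an overcast sky
#' radiates at the air temperature.
#'
#' @param air_temp_c air temperature (C).
#' @param cloud_frac cloud fraction in `[0, 1]`.
#' @param control a [tr_control()] list.
#' @return Sky temperature (C), never above `air_temp_c`.
#' @export
sky_temperature <- function(air_temp_c, cloud_frac, control = tr_control()) {
  eps_clear <- pmin(1, pmax(0.5, 0.72 + 0.005 * air_temp_c))
  eps <- (1 - cloud_frac) * eps_clear + cloud_frac
  eps^0.25 * (air_temp_c + 273.15) - 273.15
}

#' Diagnostic ground-surface temperature
#'
#' Air temperature plus a solar-driven offset, clamped to at most 0 C
#' when snow is present.
#'
#' @param air_temp_c air temperature (C).
#' @param solar_wm2 global solar flux (W/m2).
#' @param snow logical snow presence.
#' @param control a [tr_control()] list.
#' @return Ground surface temperature (C).
#' @export
ground_temperature <- function(air_temp_c, solar_wm2, snow,
                               control = tr_control()) {
  tg <- air_temp_c + control$ground_solar_gain_c_per_wm2 * solar_wm2
  ifelse(snow, pmin(tg, 0), tg)
}

#' Build one mid-month model day of hourly microclimate
#'
#' Composes solar geometry, the diurnal temperature sinusoid, the constant
#' water-mass humidity profile, land-cover/log-profile wind, cloud-adjusted
#' solar flux and the sky/ground longwave temperatures into 24 hourly
#' records at animal height.
#'
#' @param cell a list with the cell's climate and terrain:
#'   `lat`, `lon`, `tmin_c`, `tmax_c`, `wind_ms`, `cloud_frac`, `snow`
#'   (month-resolved vectors of length 12 or scalars), `elevation_m`,
#'   `slope_deg`, `aspect_deg`, `landcover`.
#' @param month month index 1-12.
#' @param animal_height_m animal height above ground (m).
#' @param control a [tr_control()] list.
#' @return A data.frame with 24 rows: `hour`, `air_temp_c`, `wind_ms`,
#'   `rh_pct`, `solar_wm2`, `sky_temp_c`, `ground_temp_c`, `is_daylight`,
#'   plus `is_active` (daylight + civil twilight) and `trad_c` (the mean
#'   radiant background, used by the endotherm model).
#' @export
build_day <- function(cell, month, animal_height_m = 1,
                      control = tr_control()) {
  if (!month %in% 1:12) stop("month must be in 1..12")
  pick <- function(x) if (length(x) >= 12) x[month] else x[1]
  tmin <- pick(cell$tmin_c); tmax <- pick(cell$tmax_c)
  wind <- pick(cell$wind_ms); cloud <- pick(cell$cloud_frac)
  snow <- isTRUE(as.logical(pick(cell$snow)))
  doy <- month_doy(month)
  hours <- 0:23
  sg <- solar_geometry(cell$lat, cell$lon, doy, hours)
  ta <- hourly_air_temperature(tmin, tmax, hours, sg$sunrise_h)
  rh <- hourly_humidity(ta, tmin)
  sol <- if (isTRUE(control$solar_enabled)) {
    incident_solar(sg$zenith_deg, cell$slope_deg %||% 0,
                   cell$aspect_deg %||% 0, sg$azimuth_deg, cloud, control)
  } else rep(0, 24)
  wnd <- wind_at_height(wind, cell$landcover %||% "other",
                        animal_height_m, control)
  tsky <- sky_temperature(ta, cloud, control)
  tgnd <- ground_temperature(ta, sol, snow, control)
  data.frame(
    hour = hours,
    air_temp_c = ta,
    wind_ms = rep(wnd, 24),
    rh_pct = rh,
    solar_wm2 = sol,
    sky_temp_c = tsky,
    ground_temp_c = tgnd,
    is_daylight = sg$zenith_deg < 90,
    is_active = sg$zenith_deg <= control$active_zenith_deg,
    trad_c = 0.5 * tsky + 0.5 * tgnd
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precompute the hourly microclimate arrays for a whole landscape
#'
#' Evaluates [build_day()] for every cell and month, returning dense
#' arrays indexed `[cell, month, hour]` that the gridded energetics kernel
#' consumes. Cells are in column-major grid order (row fastest).
#'
#' @param landscape a landscape as returned by [generate_landscape()].
#' @param animal_height_m animal height above ground (m).
#' @param control a [tr_control()] list.
#' @return A list of arrays `ta`, `trad`, `solar`, `rhov_air` (ambient
#'   vapor density, kg/m3), `active` plus a `[cell, month]` matrix `wind`
#'   of wind speed at animal height and the vector `ncell`.
#' @export
microclimate_grid <- function(landscape, animal_height_m = 1,
                              control = tr_control()) {
  nr <- landscape$grid_rows; nc <- landscape$grid_cols
  ncell <- nr * nc
  dims <- c(ncell, 12, 24)
  ta <- array(NA_real_, dims); trad <- array(NA_real_, dims)
  sol <- array(NA_real_, dims); rhov <- array(NA_real_, dims)
  act <- array(FALSE, dims)
  wind <- matrix(NA_real_, ncell, 12)
  lat_of_cell <- landscape$lat[(seq_len(ncell) - 1L) %% nr + 1L]
  hours <- 0:23
  for (m in 1:12) {
    doy <- month_doy(m)
    # solar geometry depends on latitude only: do it per distinct latitude
    for (la in unique(lat_of_cell)) {
      idx <- which(lat_of_cell == la)
      sg <- solar_geometry(la, 0, doy, hours)
      tmin <- landscape$tmin[, , m][idx]
      tmax <- landscape$tmax[, , m][idx]
      # scale a unit diurnal sinusoid to each cell's range
      unit <- hourly_air_temperature(0, 1, hours, sg$sunrise_h)
      tah <- outer(tmax - tmin, unit) + tmin
      ta[idx, m, ] <- tah
      cloud <- landscape$cloud[, , m][idx]
      snow <- landscape$snow[, , m][idx]
      sol_h <- if (isTRUE(control$solar_enabled)) {
        s <- incident_solar(sg$zenith_deg, 0, 0, sg$azimuth_deg, 0, control)
        outer(1 - (1 - control$overcast_transmission) * cloud, s)
      } else matrix(0, length(idx), 24)
      # slope/aspect projection is applied only for non-flat terrain
      if (!isTRUE(landscape$flat_terrain) && isTRUE(control$solar_enabled)) {
        slp <- landscape$slope[idx]; asp <- landscape$aspect[idx]
        vary <- which(slp > 1e-9)
        for (i in vary) {
          sol_h[i, ] <- incident_solar(sg$zenith_deg, slp[i], asp[i],
                                       sg$azimuth_deg, cloud[i], control)
        }
      }
      sol[idx, m, ] <- sol_h
      tsky <- sky_temperature(tah, cloud, control)
      tgnd <- ground_temperature(tah, sol_h, matrix(snow, length(idx), 24),
                                 control)
      trad[idx, m, ] <- 0.5 * tsky + 0.5 * tgnd
      rh <- pmin(100, 100 * e_sat_kpa(tmin) / e_sat_kpa(tah))
      rhov[idx, m, ] <- vapor_density(rh / 100 * e_sat_kpa(tah), tah)
      act[idx, m, ] <- matrix(rep(sg$zenith_deg <= control$active_zenith_deg,
                                  each = length(idx)), length(idx), 24)
      lc <- landscape$landcover[idx]
      wind[idx, m] <- wind_at_height(landscape$wind[, , m][idx], lc,
                                     animal_height_m, control)
    }
  }
  list(ta = ta, trad = trad, solar = sol, rhov_air = rhov,
       active = act, wind = wind, ncell = ncell,
       grid_rows = nr, grid_cols = nc)
}
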