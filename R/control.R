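#' Model configuration and physical constants
#'
#' Returns the list of numerical constants and switches shared by the
#' microclimate and endotherm models. Every tunable the solver uses lives
#' here so that the per-hour reference path and the gridded kernel are
#' parameterized identically.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Key entries (units in brackets):
#' \describe{
#'   \item{solar_constant_wm2}{Top-of-atmosphere solar flux, 1367 [W/m2].}
#'   \item{atm_transmittance}{Clear-sky broadband transmittance per unit air
#'     mass, 0.70 [-]; beam flux is \code{S0 * tau^airmass}.}
#'   \item{diffuse_fraction}{Coefficient of the diffuse term,
#'     \code{0.3 * S0 * (1 - tau^m) * cos(zenith)}.}
#'   \item{overcast_transmission}{Fraction of clear-sky solar surviving a
#'     fully overcast sky, 0.25; cloud attenuation is linear in cloud
#'     fraction between 1 and this floor.}
#'   \item{lw_lin_temp_c}{Reference temperature at which the longwave
#'     radiative coefficient \code{4*eps*sigma*T^3} is evaluated, 10 [C].
#'     Fixing it keeps the hourly heat balance closed form.}
#'   \item{emissivity}{Thermal emissivity of plumage/skin, 0.95 [-].}
#'   \item{ground_solar_gain_c_per_wm2}{Diagnostic ground-surface warming
#'     per unit global solar flux, 0.012 [C per W/m2].}
#'   \item{k_air_still, k_keratin, k_fat}{Conductivities of still air
#'     (0.0255), feather keratin (0.20) and subcutaneous fat (0.20)
#'     [W/m/C].}
#'   \item{packing_coef}{Dimensionless coefficient mapping feather geometry
#'     to the plumage packing fraction \code{phi = packing_coef *
#'     (feather_diameter/depth) * (feather_length/depth)}; effective plumage
#'     conductivity is \code{(1-phi)*k_air_still + phi*k_keratin}.}
#'   \item{forced_nu_coef, wind_exponent, free_nu}{Forced-convection
#'     Nusselt power law \code{Nu = forced_nu_coef * Re^wind_exponent}
#'     (0.615, 0.5) and the free-convection floor \code{Nu = free_nu}
#'     (3.0).}
#'   \item{roughness_length_m}{Roughness length of the neutral log wind
#'     profile used to move the 2 m reference wind to animal height,
#'     0.01 [m].}
#'   \item{albedo_ground}{Ground albedo driving the ventral
#'     ground-reflected solar load, 0.25 [-].}
#'   \item{resp_coef_per_c}{Respiratory heat loss as a fraction of
#'     metabolic rate per degree of inhaled-exhaled air temperature
#'     difference, 0.008 [1/C].}
#'   \item{delta_exhale_c}{Inhaled-exhaled air temperature difference,
#'     5 [C].}
#'   \item{vapor_resistance_factor}{Attenuation of cutaneous evaporation by
#'     the plumage vapor pathway, 0.3 [-].}
#'   \item{core_skin_dt_c}{Fixed skin-node temperature offset below core,
#'     0 [C] by default; exposed so trait-sensitivity designs can vary it.}
#'   \item{solar_enabled, evap_enabled}{Master switches used by the
#'     analytic oracles; both TRUE by default.}
#'   \item{ptiloerection_max, ptiloerection_step}{Upper bound (1.5) and
#'     step (0.1) of the plumage-depth multiplier used under cold stress.}
#'   \item{tolerance_band}{Relative half-width of the accepted error around
#'     the target metabolic rate, 0.05.}
#'   \item{active_zenith_deg}{Solar zenith at or below which a bird is
#'     considered active (daylight + civil twilight), 96 [deg].}
#'   \item{intake_window, overheat_window}{Aggregation windows of the
#'     intake-ceiling and overheating checks: "daily" and "hourly".}
#' }
#' @return A named list of class `tr_control`.
#' @export
#' @examples
#' ctl <- tr_control(solar_enabled = FALSE)
#' ctl$atm_transmittance
tr_control <- function(...) {
  ctl <- list(
    solar_constant_wm2 = 1367,
    atm_transmittance = 0.70,
    diffuse_fraction = 0.3,
    overcast_transmission = 0.25,
    lw_lin_temp_c = 10,
    emissivity = 0.95,
    sigma = 5.670374419e-8,
    ground_solar_gain_c_per_wm2 = 0.012,
    k_air_still = 0.0255,
    k_air = 0.0257,
    nu_air = 1.5e-5,
    k_keratin = 0.20,
    k_fat = 0.20,
    packing_coef = 10,
    packing_min = 0.005,
    packing_max = 0.95,
    forced_nu_coef = 0.615,
    wind_exponent = 0.5,
    free_nu = 3.0,
    roughness_length_m = 0.01,
    reference_height_m = 2,
    min_height_m = 0.05,
    albedo_ground = 0.25,
    resp_coef_per_c = 0.008,
    delta_exhale_c = 5,
    vapor_resistance_factor = 0.3,
    rho_air = 1.2,
    cp_air = 1006,
    lambda_vap = 2.43e6,
    core_skin_dt_c = 0,
    solar_enabled = TRUE,
    evap_enabled = TRUE,
    ptiloerection_max = 1.5,
    ptiloerection_step = 0.1,
    tolerance_band = 0.05,
    active_zenith_deg = 96,
    intake_window = "daily",
    overheat_window = "hourly"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(ctl))
    if (length(bad)) stop("unknown control entries: ", paste(bad, collapse = ", "))
    ctl[names(dots)] <- dots
  }
  class(ctl) <- "tr_control"
  ctl
}

#' Saturation vapor pressure (Tetens)
#'
#' @param temp_c air temperature in degrees Celsius.
#' @return Saturation vapor pressure in kPa.
#' @export
e_sat_kpa <- function(temp_c) {
  0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))
}

# vapor density (kg/m3) from vapor pressure (kPa) and temperature (C)
vapor_density <- function(e_kpa, temp_c) {
  1000 * e_kpa / (461.5 * (temp_c + 273.15))
}

# linearised radiative exchange coefficient, W/m2/K
radiative_coefficient <- function(control) {
  4 * control$emissivity * control$sigma * (control$lw_lin_temp_c + 273.15)^3
}

# fraction of metabolic rate lost as respiratory evaporation/warming
respiratory_fraction <- function(control) {
  if (!isTRUE(control$evap_enabled)) return(0)
  control$resp_coef_per_c * control$delta_exhale_c
}

#' Mid-month day of year of the 12 model days
#' @param month month index 1-12 (vectorized).
#' @return Integer day of year.
#' @export
month_doy <- function(month) {
  c(15L, 45L, 74L, 105L, 135L, 166L, 196L, 227L, 258L, 288L, 319L, 349L)[month]
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
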