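# reference body plan: mass fractions, shapes and the parakeet-reference
# plumage from which feather depth/length scale isometrically with mass
part_reference <- function() {
  list(
    torso = list(shape = "ellipsoid", mass_fraction = 0.72,
                 ratios = c(2, 1, 1), exposed = 1, bare = FALSE, fat = TRUE,
                 fd_d = 0.012, fd_v = 0.009, fl_d = 0.024, fl_v = 0.018,
                 refl_d = 0.25, refl_v = 0.35),
    neck = list(shape = "cylinder", mass_fraction = 0.10, aspect = 2,
                exposed = 1, bare = FALSE, fat = TRUE,
                fd_d = 0.005, fd_v = 0.004, fl_d = 0.012, fl_v = 0.010,
                refl_d = 0.25, refl_v = 0.35),
    head = list(shape = "ellipsoid", mass_fraction = 0.12,
                ratios = c(1.2, 1, 1), exposed = 1, bare = FALSE,
                fat = FALSE,
                fd_d = 0.005, fd_v = 0.005, fl_d = 0.010, fl_v = 0.010,
                refl_d = 0.25, refl_v = 0.35),
    leg = list(shape = "cylinder", mass_fraction = 0.05, aspect = 8,
               exposed = 0.25, bare = TRUE, fat = FALSE,
               fd_d = 0, fd_v = 0, fl_d = 0, fl_v = 0,
               refl_d = NA, refl_v = NA),
    beak = list(shape = "cylinder", mass_fraction = 0.01, aspect = 3,
                exposed = 0.40, bare = TRUE, fat = FALSE,
                fd_d = 0, fd_v = 0, fl_d = 0, fl_v = 0,
                refl_d = NA, refl_v = NA)
  )
}

reference_mass_kg <- 0.170

# Knud Thomsen approximation of the ellipsoid surface area
ellipsoid_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Derive body-part geometry from mass and density
#'
#' Each part's volume is its mass fraction times total mass over body
#' density; linear dimensions follow from the part's shape (cylinder
#' aspect ratio or ellipsoid axis ratios) by isometric scaling. When
#' measured dimensions are supplied, they are kept unchanged if the
#' density they imply is within 5% of the 875 kg/m3 reference, and
#' rescaled isometrically to match the target volume otherwise.
#'
#' @param mass_kg total body mass (kg, > 0).
#' @param density_kg_m3 whole-body density (kg/m3, > 0); default 875.
#' @param part_proportions named numeric vector of part mass fractions
#'   summing to 1; defaults to the packaged body plan.
#' @param measured optional named list of measured dimensions per part
#'   (cylinder: `length_m`, `diameter_m`; ellipsoid: `semi_axes_m`).
#' @param reference optional body-plan list as from the package default.
#' @return A named list of part geometries: shape, dimensions, total and
#'   exposed surface area, characteristic dimension and flesh depth.
#' @export
geometry_from_mass <- function(mass_kg, density_kg_m3 = 875,
                               part_proportions = NULL, measured = NULL,
                               reference = part_reference()) {
  if (mass_kg <= 0 || density_kg_m3 <= 0)
    stop("mass and density must be positive")
  if (is.null(part_proportions))
    part_proportions <- vapply(reference, `[[`, numeric(1), "mass_fraction")
  if (abs(sum(part_proportions) - 1) > 1e-6)
    stop("part mass fractions must sum to 1")
  out <- list()
  for (nm in names(reference)) {
    ref <- reference[[nm]]
    v_target <- part_proportions[[nm]] * mass_kg / density_kg_m3
    meas <- measured[[nm]]
    if (ref$shape == "cylinder") {
      if (!is.null(meas)) {
        v_meas <- pi * meas$diameter_m^2 / 4 * meas$length_m
        rho_implied <- part_proportions[[nm]] * mass_kg / v_meas
        scale <- if (abs(rho_implied - 875) / 875 <= 0.05) 1 else
          (v_target / v_meas)^(1 / 3)
        d <- meas$diameter_m * scale; l <- meas$length_m * scale
      } else {
        d <- (4 * v_target / (pi * ref$aspect))^(1 / 3)
        l <- ref$aspect * d
      }
      area <- pi * d * l
      d_char <- d
      flesh_depth <- d / 4
      dims <- list(length_m = l, diameter_m = d)
    } else {
      if (!is.null(meas)) {
        ax <- meas$semi_axes_m
        v_meas <- 4 / 3 * pi * prod(ax)
        rho_implied <- part_proportions[[nm]] * mass_kg / v_meas
        scale <- if (abs(rho_implied - 875) / 875 <= 0.05) 1 else
          (v_target / v_meas)^(1 / 3)
        ax <- ax * scale
      } else {
        s <- (v_target / (4 / 3 * pi * prod(ref$ratios)))^(1 / 3)
        ax <- ref$ratios * s
      }
      area <- ellipsoid_area(ax[1], ax[2], ax[3])
      d_char <- 2 * (3 * (4 / 3 * pi * prod(ax)) / (4 * pi))^(1 / 3)
      flesh_depth <- min(ax) / 2
      dims <- list(semi_axes_m = ax)
    }
    out[[nm]] <- c(list(name = nm, shape = ref$shape,
                        mass_fraction = part_proportions[[nm]],
                        area_m2 = area,
                        exposed_fraction = ref$exposed,
                        area_eff_m2 = area * ref$exposed,
                        d_char_m = d_char, flesh_depth_m = flesh_depth,
                        bare = ref$bare, has_fat = ref$fat), dims)
  }
  out
}

#' Construct a bird trait set
#'
#' Assembles morphology (via [geometry_from_mass()]), plumage, physiology
#' and the fixed behavioural/physiological constants of the endotherm
#' model into one object. Feather depths and lengths scale isometrically
#' (mass^(1/3)) from the 170 g reference plumage unless supplied.
#'
#' @param species species label.
#' @param mass_kg body mass (kg).
#' @param core_temp_c core body temperature Tb (C).
#' @param bmr_w basal metabolic rate (W).
#' @param body_density_kg_m3 whole-body density; default 875 kg/m3.
#' @param fat_fraction subcutaneous fat fraction on neck and torso.
#' @param feather_depth_scale,feather_length_scale optional multipliers on
#'   feather depths and lengths (on top of the isometric mass scaling).
#' @param reflectivity_scale optional multiplier on feathered-part solar
#'   reflectivities.
#' @param feather_diameter_m feather element diameter entering the plumage
#'   packing fraction.
#' @param breeding_duration_months breeding-cycle duration, months
#'   (integer, >= 1; durations from the literature are rounded up).
#' @param animal_height_m height above ground the bird experiences.
#' @param k_flesh_min,k_flesh_max flesh thermal conductivity bounds
#'   (vasoconstriction/vasodilation), W/m/C.
#' @param activity_multiplier,breeding_multiplier,intake_ceiling_multiplier
#'   BMR multipliers: foraging activity (2.5), breeding (1.5) and the
#'   maximal sustained intake (4.6).
#' @param wet_skin_min,wet_skin_max fraction of skin acting as free water
#'   surface (1% baseline, up to 5% under heat stress).
#' @param muscle_efficiency fraction of active metabolic power exported as
#'   mechanical work (0.25).
#' @param bare_part_reflectivity solar reflectivity of legs and beak
#'   (0.33).
#' @param measured optional measured dimensions (see
#'   [geometry_from_mass()]).
#' @param seed integer recorded with the traits.
#' @return A list of class `bird_traits`.
#' @export
bird_traits <- function(species, mass_kg, core_temp_c, bmr_w,
                        body_density_kg_m3 = 875,
                        fat_fraction = 0.10,
                        feather_depth_scale = 1,
                        feather_length_scale = 1,
                        reflectivity_scale = 1,
                        feather_diameter_m = 3e-5,
                        breeding_duration_months = 3L,
                        animal_height_m = 1,
                        k_flesh_min = 0.41, k_flesh_max = 2.80,
                        activity_multiplier = 2.5,
                        breeding_multiplier = 1.5,
                        intake_ceiling_multiplier = 4.6,
                        wet_skin_min = 0.01, wet_skin_max = 0.05,
                        muscle_efficiency = 0.25,
                        bare_part_reflectivity = 0.33,
                        measured = NULL,
                        seed = 1L) {
  if (mass_kg <= 0 || bmr_w <= 0) stop("mass and BMR must be positive")
  if (k_flesh_min > k_flesh_max) stop("k_flesh_min must be <= k_flesh_max")
  if (fat_fraction < 0 || fat_fraction >= 1)
    stop("fat_fraction must be in [0,1)")
  if (any(c(activity_multiplier, breeding_multiplier,
            intake_ceiling_multiplier) <= 0))
    stop("multipliers must be positive")
  breeding_duration_months <- as.integer(ceiling(breeding_duration_months))
  if (breeding_duration_months < 1) stop("breeding duration must be >= 1")
  ref <- part_reference()
  geom <- geometry_from_mass(mass_kg, body_density_kg_m3,
                             measured = measured, reference = ref)
  iso <- (mass_kg / reference_mass_kg)^(1 / 3)
  fdc <- feather_depth_scale * iso
  flc <- feather_length_scale * iso
  parts <- lapply(names(geom), function(nm) {
    p <- geom[[nm]]; r <- ref[[nm]]
    p$feather_depth_dorsal_m <- r$fd_d * fdc
    p$feather_depth_ventral_m <- r$fd_v * fdc
    p$feather_length_dorsal_m <- r$fl_d * flc
    p$feather_length_ventral_m <- r$fl_v * flc
    if (p$bare) {
      p$refl_dorsal <- bare_part_reflectivity
      p$refl_ventral <- bare_part_reflectivity
    } else {
      p$refl_dorsal <- min(1, r$refl_d * reflectivity_scale)
      p$refl_ventral <- min(1, r$refl_v * reflectivity_scale)
    }
    p
  })
  names(parts) <- names(geom)
  structure(list(
    species = species, mass_kg = mass_kg,
    body_density_kg_m3 = body_density_kg_m3,
    fat_fraction = fat_fraction, core_temp_c = core_temp_c, bmr_w = bmr_w,
    k_flesh_min = k_flesh_min, k_flesh_max = k_flesh_max,
    flesh_specific_heat = 4185, muscle_efficiency = muscle_efficiency,
    wet_skin_min = wet_skin_min, wet_skin_max = wet_skin_max,
    activity_multiplier = activity_multiplier,
    breeding_multiplier = breeding_multiplier,
    intake_ceiling_multiplier = intake_ceiling_multiplier,
    bare_part_reflectivity = bare_part_reflectivity,
    feather_diameter_m = feather_diameter_m,
    breeding_duration_months = breeding_duration_months,
    animal_height_m = animal_height_m,
    parts = parts, seed = seed), class = "bird_traits")
}

#' @export
print.bird_traits <- function(x, ...) {
  cat("bird_traits:", x$species, "\n")
  cat(sprintf("  mass %.4g kg, Tb %.1f C, BMR %.3g W, height %.2f m\n",
              x$mass_kg, x$core_temp_c, x$bmr_w, x$animal_height_m))
  cat("  parts:", paste(names(x$parts), collapse = ", "), "\n")
  invisible(x)
}

#' Construct and validate a thermoregulatory state
#'
#' @param k_flesh flesh conductivity (W/m/C) within the trait bounds.
#' @param plumage_depth_multiplier ptiloerection multiplier in
#'   `[1, ptiloerection_max]`.
#' @param wet_skin_fraction wet-skin fraction within the trait bounds.
#' @param in_shade logical; shade removes solar gain only.
#' @param traits a `bird_traits` (for the bounds).
#' @param control a [tr_control()] list.
#' @return A list of class `thermo_state`.
#' @export
thermo_state <- function(k_flesh, plumage_depth_multiplier = 1,
                         wet_skin_fraction = NULL, in_shade = FALSE,
                         traits, control = tr_control()) {
  if (is.null(wet_skin_fraction)) wet_skin_fraction <- traits$wet_skin_min
  if (k_flesh < traits$k_flesh_min - 1e-12 ||
      k_flesh > traits$k_flesh_max + 1e-12)
    stop("k_flesh outside trait bounds")
  if (plumage_depth_multiplier < 1 - 1e-12 ||
      plumage_depth_multiplier > control$ptiloerection_max + 1e-12)
    stop("plumage depth multiplier out of bounds")
  if (wet_skin_fraction < traits$wet_skin_min - 1e-12 ||
      wet_skin_fraction > traits$wet_skin_max + 1e-12)
    stop("wet skin fraction out of bounds")
  structure(list(k_flesh = k_flesh,
                 plumage_depth_multiplier = plumage_depth_multiplier,
                 wet_skin_fraction = wet_skin_fraction,
                 in_shade = isTRUE(in_shade)),
            class = "thermo_state")
}

neutral_state <- function(traits, control = tr_control()) {
  thermo_state(k_flesh = (traits$k_flesh_min + traits$k_flesh_max) / 2,
               plumage_depth_multiplier = 1,
               wet_skin_fraction = traits$wet_skin_min,
               in_shade = FALSE, traits = traits, control = control)
}

# effective plumage conductivity from the packing-fraction interpolation
plumage_conductivity <- function(part, traits, control) {
  depth <- (part$feather_depth_dorsal_m + part$feather_depth_ventral_m) / 2
  len <- (part$feather_length_dorsal_m + part$feather_length_ventral_m) / 2
  phi <- control$packing_coef * (traits$feather_diameter_m / depth) *
    (len / depth)
  phi <- min(control$packing_max, max(control$packing_min, phi))
  (1 - phi) * control$k_air_still + phi * control$k_keratin
}

#' Series insulation resistance of one body part
#'
#' Area-specific resistance (K m2/W) of the flesh layer, the subcutaneous
#' fat layer (neck and torso only) and the plumage, in series. The plumage
#' term is the dorsoventral-mean feather depth times the ptiloerection
#' multiplier over the effective plumage conductivity, itself a linear
#' interpolation between still air and feather keratin weighted by the
#' packing fraction. Bare parts (legs, beak) contribute the flesh term
#' only.
#'
#' @param part one element of `traits$parts`.
#' @param state a [thermo_state()].
#' @param k_flesh flesh conductivity (W/m/C) actually in effect.
#' @param traits the `bird_traits`.
#' @param control a [tr_control()] list.
#' @return Resistance in K m2/W.
#' @export
insulation_resistance <- function(part, state, k_flesh, traits,
                                  control = tr_control()) {
  if (part$flesh_depth_m <= 0) stop("zero-depth flesh layer")
  r <- part$flesh_depth_m / k_flesh
  if (isTRUE(part$has_fat) && traits$fat_fraction > 0) {
    r <- r + traits$fat_fraction * 2 * part$flesh_depth_m / control$k_fat
  }
  if (!part$bare) {
    depth <- (part$feather_depth_dorsal_m + part$feather_depth_ventral_m) / 2
    r <- r + depth * state$plumage_depth_multiplier /
      plumage_conductivity(part, traits, control)
  }
  r
}

#' Convective heat-transfer coefficient
#'
#' Forced-convection power law `Nu = 0.615 * Re^0.5` for a
#' cylinder/ellipsoid of characteristic dimension `d`, floored by the
#' free-convection minimum `Nu = 3`.
#'
#' @param wind_ms wind speed at animal height (m/s, >= 0).
#' @param characteristic_dimension_m diameter (cylinder) or
#'   volume-equivalent sphere diameter (ellipsoid), m.
#' @param air_temp_c air temperature (C); accepted for interface
#'   completeness (air properties are held at their reference values).
#' @param control a [tr_control()] list.
#' @return Coefficient in W/m2/K, strictly increasing in wind above the
#'   floor.
#' @export
convective_coefficient <- function(wind_ms, characteristic_dimension_m,
                                   air_temp_c = 15,
                                   control = tr_control()) {
  if (any(wind_ms < 0)) stop("wind must be >= 0")
  if (any(characteristic_dimension_m <= 0)) stop("dimension must be > 0")
  d <- characteristic_dimension_m
  h_free <- control$free_nu * control$k_air / d
  re <- wind_ms * d / control$nu_air
  h_forced <- control$forced_nu_coef * control$k_air / d *
    re^control$wind_exponent
  pmax(h_free, h_forced)
}

#' Solve the steady-state heat balance for one hour
#'
#' Computes the metabolic rate `M` that holds core temperature given the
#' hourly microclimate, the current thermoregulatory state and the
#' conduction chain core -> skin -> plumage surface of every body part
#' solved in parallel (one shared core temperature, no part-to-part
#' conduction). Longwave exchange is linearized at a fixed reference
#' temperature so the balance
#' `M*(1 - eta) + S_abs = C + L + E_cut + E_resp` is closed form:
#' `M = (Q_dry + E_cut) / (1 - eta - f_resp)` with `Q_dry` the series
#' conductance loss summed over parts, `eta` the muscle work export
#' during active hours, and `E_resp = f_resp * M`.
#'
#' @param traits a `bird_traits`.
#' @param state a [thermo_state()].
#' @param mc one hourly microclimate record (a one-row data.frame or list
#'   with `air_temp_c`, `wind_ms`, `rh_pct`, `solar_wm2`, `sky_temp_c`,
#'   `ground_temp_c` and optionally `is_active`).
#' @param control a [tr_control()] list.
#' @return A list of class `heat_balance`: `m_required_w`, the flux
#'   breakdown (`solar_absorbed_w`, `convection_w`, `net_longwave_w`,
#'   `cutaneous_evap_w`, `respiratory_evap_w`), per-part surface and skin
#'   temperatures, the `state`, `status` (always `"balanced"` here) and
#'   the energy residual `residual_w`.
#' @export
solve_heat_balance <- function(traits, state, mc, control = tr_control()) {
  ta <- mc$air_temp_c
  trad <- if (!is.null(mc$trad_c)) mc$trad_c else
    0.5 * (mc$sky_temp_c + mc$ground_temp_c)
  sol <- if (isTRUE(control$solar_enabled)) mc$solar_wm2 else 0
  active <- isTRUE(mc$is_active)
  hr <- radiative_coefficient(control)
  tb <- traits$core_temp_c - control$core_skin_dt_c

  q_dry <- 0; s_tot <- 0; conv <- 0; lw <- 0; evap_cond <- 0
  ts_surface <- numeric(length(traits$parts))
  ts_skin <- numeric(length(traits$parts))
  for (i in seq_along(traits$parts)) {
    p <- traits$parts[[i]]
    hc <- convective_coefficient(mc$wind_ms, p$d_char_m, ta, control)
    hx <- hc + hr
    rins <- insulation_resistance(p, state, state$k_flesh, traits, control)
    s_abs <- if (sol > 0 && !state$in_shade) {
      0.5 * p$area_eff_m2 *
        ((1 - p$refl_dorsal) + (1 - p$refl_ventral) * control$albedo_ground) *
        sol
    } else 0
    te <- (hc * ta + hr * trad) / hx + s_abs / (p$area_eff_m2 * hx)
    flux <- (tb - te) / (rins + 1 / hx)           # W/m2 through the part
    q <- p$area_eff_m2 * flux
    ts <- tb - flux * rins
    q_dry <- q_dry + q
    s_tot <- s_tot + s_abs
    conv <- conv + hc * p$area_eff_m2 * (ts - ta)
    lw <- lw + hr * p$area_eff_m2 * (ts - trad)
    ts_surface[i] <- ts
    r_inner <- p$flesh_depth_m / state$k_flesh +
      if (isTRUE(p$has_fat) && traits$fat_fraction > 0)
        traits$fat_fraction * 2 * p$flesh_depth_m / control$k_fat else 0
    ts_skin[i] <- tb - flux * r_inner
    evap_cond <- evap_cond + p$area_eff_m2 * hc
  }
  e_cut <- 0
  if (isTRUE(control$evap_enabled)) {
    rhov_skin <- vapor_density(e_sat_kpa(tb), tb)
    rhov_air <- vapor_density(mc$rh_pct / 100 * e_sat_kpa(ta), ta)
    lewis <- control$lambda_vap / (control$rho_air * control$cp_air) *
      control$vapor_resistance_factor
    e_cut <- state$wet_skin_fraction * evap_cond * lewis *
      max(0, rhov_skin - rhov_air)
  }
  f_resp <- respiratory_fraction(control)
  eta <- if (active) traits$muscle_efficiency else 0
  m <- (q_dry + e_cut) / (1 - eta - f_resp)
  e_resp <- f_resp * m
  residual <- m * (1 - eta) + s_tot - conv - lw - e_cut - e_resp
  structure(list(
    m_required_w = m,
    solar_absorbed_w = s_tot, convection_w = conv, net_longwave_w = lw,
    cutaneous_evap_w = e_cut, respiratory_evap_w = e_resp,
    surface_temp_c = stats::setNames(ts_surface, names(traits$parts)),
    skin_temp_c = stats::setNames(ts_skin, names(traits$parts)),
    state = state, status = "balanced", residual_w = residual),
    class = "heat_balance")
}

# ordered candidate states of the thermoregulatory cascade
cascade_states <- function(traits, control) {
  cold <- list(thermo_state(traits$k_flesh_min, 1, traits$wet_skin_min,
                            FALSE, traits, control))
  mults <- seq(1 + control$ptiloerection_step, control$ptiloerection_max,
               by = control$ptiloerection_step)
  for (pm in mults) {
    cold <- c(cold, list(thermo_state(traits$k_flesh_min, pm,
                                      traits$wet_skin_min, FALSE,
                                      traits, control)))
  }
  hot <- list(
    thermo_state(traits$k_flesh_max, 1, traits$wet_skin_min, FALSE,
                 traits, control),
    thermo_state(traits$k_flesh_max, 1, traits$wet_skin_max, FALSE,
                 traits, control),
    thermo_state(traits$k_flesh_max, 1, traits$wet_skin_max, TRUE,
                 traits, control))
  list(neutral = neutral_state(traits, control), cold = cold, hot = hot)
}

#' Thermoregulatory cascade towards a target metabolic rate
#'
#' Starting from the neutral state (mid-range flesh conductivity, no
#' ptiloerection, baseline wet skin, no shade), applies the ordered
#' physiological-then-behavioural adjustments until the solved metabolic
#' rate falls within +/-5% of the target: under cold stress full
#' vasoconstriction first, then stepwise ptiloerection; under heat stress
#' vasodilation, then maximal skin wetting, then shade. If no state lands
#' in the band the extreme state is returned; when even the extreme hot
#' state leaves the allowable rate below BMR the status is `heat_death`
#' (death from cold is decided later against the intake ceiling).
#'
#' @param traits a `bird_traits`.
#' @param mc one hourly microclimate record (see [solve_heat_balance()]).
#' @param target_m_w target metabolic rate (W, > 0).
#' @param control a [tr_control()] list.
#' @return A `heat_balance` result (with `status` possibly
#'   `"heat_death"`).
#' @export
thermoregulate <- function(traits, mc, target_m_w,
                           control = tr_control()) {
  if (target_m_w <= 0) stop("target metabolic rate must be positive")
  band <- control$tolerance_band
  states <- cascade_states(traits, control)
  res <- solve_heat_balance(traits, states$neutral, mc, control)
  in_band <- function(m) abs(m - target_m_w) <= band * target_m_w
  if (in_band(res$m_required_w)) return(res)
  if (res$m_required_w > (1 + band) * target_m_w) {
    for (st in states$cold) {
      res <- solve_heat_balance(traits, st, mc, control)
      if (in_band(res$m_required_w)) return(res)
    }
    return(res)   # cold extreme; the intake ceiling decides survival
  }
  for (st in states$hot) {
    res <- solve_heat_balance(traits, st, mc, control)
    if (in_band(res$m_required_w)) return(res)
  }
  if (res$m_required_w < traits$bmr_w) res$status <- "heat_death"
  res
}
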