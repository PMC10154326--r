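# Build the per-variant coefficient rows consumed by the compiled
# energetics kernel. One row per trait/control pair; the state order is
# exactly that of cascade_states().
variant_coefficients <- function(traits_list, control_list) {
  nvar <- length(traits_list)
  p0 <- traits_list[[1]]$parts
  P <- length(p0)
  states0 <- cascade_states(traits_list[[1]], control_list[[1]])
  seq_states <- c(list(states0$neutral), states0$cold, states0$hot)
  S <- length(seq_states)
  ncold <- length(states0$cold)
  scal <- matrix(0, nvar, 10)
  areaEff <- matrix(0, nvar, P); hfree <- matrix(0, nvar, P)
  hforc <- matrix(0, nvar, P); solc <- matrix(0, nvar, P)
  rins <- matrix(0, nvar, P * S); wet <- matrix(0, nvar, S)
  shade <- logical(S)
  for (v in seq_len(nvar)) {
    tr <- traits_list[[v]]; ctl <- control_list[[v]]
    states <- cascade_states(tr, ctl)
    seqs <- c(list(states$neutral), states$cold, states$hot)
    if (length(seqs) != S) stop("variant state counts differ")
    f_resp <- respiratory_fraction(ctl)
    tb <- tr$core_temp_c - ctl$core_skin_dt_c
    lewis <- if (isTRUE(ctl$evap_enabled)) {
      ctl$lambda_vap / (ctl$rho_air * ctl$cp_air) *
        ctl$vapor_resistance_factor
    } else 0
    scal[v, ] <- c(tb, vapor_density(e_sat_kpa(tb), tb),
                   tr$muscle_efficiency, f_resp,
                   tr$activity_multiplier, tr$breeding_multiplier,
                   tr$bmr_w, tr$intake_ceiling_multiplier,
                   tr$breeding_duration_months, lewis)
    for (p in seq_len(P)) {
      pt <- tr$parts[[p]]
      areaEff[v, p] <- pt$area_eff_m2
      hfree[v, p] <- ctl$free_nu * ctl$k_air / pt$d_char_m
      hforc[v, p] <- ctl$forced_nu_coef * ctl$k_air / pt$d_char_m *
        (pt$d_char_m / ctl$nu_air)^ctl$wind_exponent
      solc[v, p] <- if (isTRUE(ctl$solar_enabled)) {
        0.5 * pt$area_eff_m2 * ((1 - pt$refl_dorsal) +
                                  (1 - pt$refl_ventral) * ctl$albedo_ground)
      } else 0
      for (s in seq_len(S)) {
        st <- seqs[[s]]
        rins[v, (s - 1) * P + p] <-
          insulation_resistance(pt, st, st$k_flesh, tr, ctl)
      }
    }
    wet[v, ] <- vapply(seqs, `[[`, numeric(1), "wet_skin_fraction")
  }
  shade[] <- vapply(seq_states, `[[`, logical(1), "in_shade")
  list(scal = scal, areaEff = areaEff, hfree = hfree, hforc = hforc,
       solc = solc, rins = rins, wet = wet, shade = shade,
       ncold = ncold, S = S, P = P)
}

#' Run the gridded energetics kernel
#'
#' Low-level batched evaluation of the hourly thermoregulatory cascade
#' over every cell and model day of a precomputed microclimate, for one or
#' many trait variants. Most users call [map_species()],
#' [evaluate_variants()] or [intraspecific_map()] instead.
#'
#' @param env precomputed microclimate from [microclimate_grid()].
#' @param traits_list list of `bird_traits` (one per variant).
#' @param control_list list of [tr_control()] objects, one per variant, or
#'   a single control recycled to all variants.
#' @param detailed logical; when TRUE (single variant only) per-month
#'   survival/breeding flags and daily multiples are returned.
#' @return A list with `at_risk` and `max_monthly_multiple`
#'   (cell x variant matrices), `fraction_at_risk` per variant, and the
#'   detailed monthly outputs when requested.
#' @export
grid_energetics <- function(env, traits_list, control_list = tr_control(),
                            detailed = FALSE) {
  if (inherits(traits_list, "bird_traits")) traits_list <- list(traits_list)
  if (inherits(control_list, "tr_control"))
    control_list <- rep(list(control_list), length(traits_list))
  stopifnot(length(control_list) == length(traits_list))
  co <- variant_coefficients(traits_list, control_list)
  ctl <- control_list[[1]]
  grid_energetics_cpp(
    as.numeric(env$ta), as.numeric(env$trad), as.numeric(env$solar),
    as.numeric(env$rhov_air), as.logical(env$active), env$wind,
    env$ncell, co$scal, co$areaEff, co$hfree, co$hforc, co$solc,
    co$rins, co$wet, co$shade, co$ncold,
    radiative_coefficient(ctl), ctl$wind_exponent, ctl$tolerance_band,
    detailed)
}
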