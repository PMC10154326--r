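#' Monthly energetics of one cell
#'
#' Reference (per-hour) evaluation of one cell-month: for each of the 24
#' hours of the mid-month model day the thermoregulatory cascade is run
#' against the hourly target (activity multiplier times BMR during
#' daylight and civil twilight, BMR otherwise; times the breeding
#' multiplier when breeding), and the monthly survival checks are applied:
#' the daily mean requirement must not exceed the intake ceiling
#' (4.6 x BMR) and no hour may leave the allowable rate below BMR.
#'
#' @param traits a `bird_traits`.
#' @param cell a cell description accepted by [build_day()].
#' @param month month 1-12.
#' @param breeding logical; apply the breeding multiplier.
#' @param control a [tr_control()] list.
#' @return A list of class `month_energetics`: `month`,
#'   `hourly_m_required_w` (24 values), `daily_mean_multiple_of_bmr`,
#'   `survival_ok`, `breeding_ok` (identical flags evaluated at this
#'   month's target mode), and `failure_reason` in
#'   `none / exceeds_intake / below_bmr`.
#' @export
month_energetics <- function(traits, cell, month, breeding = FALSE,
                             control = tr_control()) {
  day <- build_day(cell, month, traits$animal_height_m, control)
  m_req <- numeric(24)
  overheat <- FALSE
  for (h in seq_len(24)) {
    target <- traits$bmr_w *
      (if (day$is_active[h]) traits$activity_multiplier else 1) *
      (if (breeding) traits$breeding_multiplier else 1)
    res <- thermoregulate(traits, day[h, ], target, control)
    m_req[h] <- res$m_required_w
    if (identical(res$status, "heat_death")) overheat <- TRUE
  }
  mult <- mean(m_req) / traits$bmr_w
  exceeds <- mult > traits$intake_ceiling_multiplier
  ok <- !overheat && !exceeds
  structure(list(
    month = month, hourly_m_required_w = m_req,
    daily_mean_multiple_of_bmr = mult,
    survival_ok = ok, breeding_ok = ok,
    failure_reason = if (ok) "none" else
      if (overheat) "below_bmr" else "exceeds_intake"),
    class = "month_energetics")
}

#' Pixel-level invasion-risk rule
#'
#' A pixel is at risk of invasion only when the climate allows survival in
#' all twelve months and a run of at least `breeding_duration_months`
#' consecutive breeding-suitable months exists, December wrapping into
#' January.
#'
#' @param traits a `bird_traits` (provides the breeding duration).
#' @param survival_ok,breeding_ok logical vectors of length 12.
#' @return TRUE/FALSE.
#' @export
pixel_at_risk <- function(traits, survival_ok, breeding_ok) {
  if (length(survival_ok) != 12 || length(breeding_ok) != 12)
    stop("exactly 12 months required")
  if (!all(survival_ok)) return(FALSE)
  d <- traits$breeding_duration_months
  for (s in 1:12) {
    idx <- ((s - 1 + seq_len(d) - 1) %% 12) + 1
    if (all(breeding_ok[idx])) return(TRUE)
  }
  FALSE
}

#' Map energetic suitability for a species over a landscape
#'
#' Runs the gridded energetics kernel for every cell: per month, hourly
#' thermoregulation against the survival and breeding targets; per pixel,
#' the year-round-survival plus consecutive-breeding rule. For sexually
#' dimorphic species pass a list of per-sex trait sets; a pixel is then at
#' risk only when every sex's demands can be met.
#'
#' @param traits a `bird_traits` or a list of them (one per sex).
#' @param landscape a `tr_landscape`.
#' @param control a [tr_control()] list.
#' @param env optional precomputed [microclimate_grid()] at the species'
#'   animal height (recomputed per sex otherwise).
#' @return A list of class `suitability_map`: logical matrix `at_risk`,
#'   numeric matrix `max_monthly_multiple` (worst monthly daily-mean
#'   multiple of BMR; max over sexes), per-sex `survival_ok` /
#'   `breeding_ok` cell x month matrices, `fraction_at_risk` and
#'   `cells_at_risk`.
#' @export
map_species <- function(traits, landscape, control = tr_control(),
                        env = NULL) {
  sexes <- if (inherits(traits, "bird_traits")) list(traits) else traits
  nr <- landscape$grid_rows; nc <- landscape$grid_cols
  at_risk <- NULL; maxmult <- NULL
  per_sex <- list()
  for (s in seq_along(sexes)) {
    tr <- sexes[[s]]
    env_s <- if (is.null(env))
      microclimate_grid(landscape, tr$animal_height_m, control) else env
    res <- grid_energetics(env_s, tr, control, detailed = TRUE)
    risk_s <- matrix(res$at_risk[, 1], nr, nc)
    mult_s <- matrix(res$max_monthly_multiple[, 1], nr, nc)
    at_risk <- if (is.null(at_risk)) risk_s else (at_risk & risk_s)
    maxmult <- if (is.null(maxmult)) mult_s else pmax(maxmult, mult_s)
    per_sex[[s]] <- list(survival_ok = res$survival_ok,
                         breeding_ok = res$breeding_ok,
                         daily_mean_multiple = res$daily_mean_multiple,
                         failure_reason = res$failure_reason)
  }
  structure(list(
    at_risk = at_risk, max_monthly_multiple = maxmult,
    per_sex = per_sex,
    cells_at_risk = sum(at_risk), fraction_at_risk = mean(at_risk),
    grid_rows = nr, grid_cols = nc),
    class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("suitability map: %d x %d cells, %d at risk (%.1f%%)\n",
              x$grid_rows, x$grid_cols, x$cells_at_risk,
              100 * x$fraction_at_risk))
  invisible(x)
}

#' Write a per-species suitability summary CSV
#'
#' @param map a `suitability_map`.
#' @param species species label.
#' @param path output path.
#' @param sex sex label (or `"both"`).
#' @return The path, invisibly.
#' @export
write_suitability_summary <- function(map, species, path, sex = "both") {
  utils::write.csv(data.frame(
    species = species, sex = sex,
    cells_at_risk = map$cells_at_risk,
    fraction_at_risk = map$fraction_at_risk), path, row.names = FALSE)
  invisible(path)
}

#' Extract one cell's climate/terrain for the per-hour reference path
#'
#' @param landscape a `tr_landscape`.
#' @param cell cell index (column-major, row fastest).
#' @return A list accepted by [build_day()] and [month_energetics()].
#' @export
landscape_cell <- function(landscape, cell) {
  nr <- landscape$grid_rows
  r <- (cell - 1L) %% nr + 1L; cc <- (cell - 1L) %/% nr + 1L
  list(lat = landscape$lat[r], lon = landscape$lon[cc],
       tmin_c = landscape$tmin[r, cc, ], tmax_c = landscape$tmax[r, cc, ],
       wind_ms = landscape$wind[r, cc, ], cloud_frac = landscape$cloud[r, cc, ],
       snow = landscape$snow[r, cc, ],
       elevation_m = landscape$elevation[r, cc],
       slope_deg = if (isTRUE(landscape$flat_terrain)) 0 else
         landscape$slope[r, cc],
       aspect_deg = if (isTRUE(landscape$flat_terrain)) 0 else
         landscape$aspect[r, cc],
       landcover = landscape$landcover[r, cc])
}
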