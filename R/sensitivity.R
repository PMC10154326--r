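# the trait set varied by the sensitivity workflow; each name maps to a
# bird_traits argument or a control entry
lhs_parameter_names <- function() {
  c("bmr_w", "activity_multiplier", "mass_kg", "body_density_kg_m3",
    "fat_fraction", "core_temp_c", "core_skin_dt_c", "feather_diameter_m",
    "feather_length_scale", "feather_depth_scale", "reflectivity_scale",
    "delta_exhale_c")
}

#' Default sensitivity ranges around a trait set
#'
#' Ranges mirror the role of a measured-trait table: most parameters vary
#' +/-20% around the species value, bounded fractions stay within their
#' physical limits.
#'
#' @param traits a `bird_traits`.
#' @return Named list of `c(min, max)` ranges covering the full varied
#'   trait set.
#' @export
default_trait_ranges <- function(traits) {
  list(
    bmr_w = traits$bmr_w * c(0.8, 1.2),
    activity_multiplier = traits$activity_multiplier * c(0.8, 1.2),
    mass_kg = traits$mass_kg * c(0.8, 1.2),
    body_density_kg_m3 = c(830, 920),
    fat_fraction = c(0.02, 0.25),
    core_temp_c = traits$core_temp_c + c(-1.5, 1.5),
    core_skin_dt_c = c(0, 3),
    feather_diameter_m = c(2e-5, 5e-5),
    feather_length_scale = c(0.8, 1.2),
    feather_depth_scale = c(0.8, 1.2),
    reflectivity_scale = c(0.8, 1.2),
    delta_exhale_c = c(2, 10)
  )
}

#' Latin Hypercube design over trait ranges
#'
#' Stratified design with the Latin property: each parameter's `n` samples
#' occupy the `n` equal-probability strata of its range exactly once.
#' Default sizes follow the workflow: 1000 variants at the species level,
#' 100 for the intraspecific ensemble.
#'
#' @param ranges named list of `c(min, max)` ranges.
#' @param n number of variants (>= 1); default 1000.
#' @param seed integer seed.
#' @return A list of class `lhs_design`: `params`, `ranges`, the
#'   `n x k` `matrix`, and `seed`.
#' @export
lhs_sample <- function(ranges, n = 1000, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  k <- length(ranges)
  if (k == 0) stop("empty ranges")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r))) stop("invalid range: ", nm)
    if (r[1] > r[2]) stop("inverted range: ", nm)
  }
  u <- with_seed(seed, lhs::randomLHS(n, k))
  m <- sapply(seq_len(k), function(j) {
    r <- ranges[[j]]
    r[1] + u[, j] * (r[2] - r[1])
  })
  m <- matrix(m, nrow = n, ncol = k)
  colnames(m) <- names(ranges)
  structure(list(params = names(ranges), ranges = ranges,
                 matrix = m, seed = seed), class = "lhs_design")
}

#' Apply one variant's parameter vector to a trait set
#'
#' Trait parameters override the base `bird_traits` (mass rescales all
#' body-part geometry and, isometrically, feather depths and lengths);
#' the core-skin temperature differential and the inhaled-exhaled air
#' temperature difference override the corresponding control entries.
#'
#' @param traits base `bird_traits`.
#' @param values named numeric vector of parameter values (any subset of
#'   the varied set).
#' @param control base [tr_control()].
#' @return A list with elements `traits` and `control`.
#' @export
apply_variant <- function(traits, values, control = tr_control()) {
  g <- function(nm, def) if (nm %in% names(values)) unname(values[[nm]]) else def
  ctl <- control
  ctl$core_skin_dt_c <- g("core_skin_dt_c", control$core_skin_dt_c)
  ctl$delta_exhale_c <- g("delta_exhale_c", control$delta_exhale_c)
  tr <- bird_traits(
    species = traits$species,
    mass_kg = g("mass_kg", traits$mass_kg),
    core_temp_c = g("core_temp_c", traits$core_temp_c),
    bmr_w = g("bmr_w", traits$bmr_w),
    body_density_kg_m3 = g("body_density_kg_m3", traits$body_density_kg_m3),
    fat_fraction = g("fat_fraction", traits$fat_fraction),
    feather_depth_scale = g("feather_depth_scale", 1),
    feather_length_scale = g("feather_length_scale", 1),
    reflectivity_scale = g("reflectivity_scale", 1),
    feather_diameter_m = g("feather_diameter_m", traits$feather_diameter_m),
    breeding_duration_months = traits$breeding_duration_months,
    animal_height_m = traits$animal_height_m,
    activity_multiplier = g("activity_multiplier",
                            traits$activity_multiplier),
    breeding_multiplier = traits$breeding_multiplier,
    intake_ceiling_multiplier = traits$intake_ceiling_multiplier,
    seed = traits$seed)
  list(traits = tr, control = ctl)
}

#' Evaluate every variant of a design against occurrence data
#'
#' Each variant's trait vector overrides the base species, the suitability
#' map is computed, and the True Skill Statistic (sensitivity +
#' specificity - 1) is evaluated against presence cells versus background
#' cells, together with the fraction of the landscape classified at risk.
#'
#' @param design an [lhs_sample()] design.
#' @param traits base `bird_traits`.
#' @param landscape a `tr_landscape`.
#' @param occurrences occurrence data.frame (or integer cell indices).
#' @param background background cell indices; default all cells.
#' @param control a [tr_control()] list.
#' @param env optional precomputed [microclimate_grid()] (all variants
#'   share the species' animal height).
#' @return A data.frame of class `variant_results`: `variant_id`, one
#'   column per parameter, `tss`, `fraction_area_at_risk`.
#' @export
evaluate_variants <- function(design, traits, landscape, occurrences,
                              background = NULL, control = tr_control(),
                              env = NULL) {
  cells <- if (is.numeric(occurrences)) as.integer(occurrences) else
    occurrence_cells(occurrences, landscape)
  ncell <- landscape$grid_rows * landscape$grid_cols
  if (any(cells < 1 | cells > ncell)) stop("occurrences outside landscape")
  if (is.null(background)) background <- seq_len(ncell)
  if (is.null(env))
    env <- microclimate_grid(landscape, traits$animal_height_m, control)
  n <- nrow(design$matrix)
  variants <- lapply(seq_len(n), function(i)
    apply_variant(traits, design$matrix[i, ], control))
  res <- grid_energetics(env,
                         lapply(variants, `[[`, "traits"),
                         lapply(variants, `[[`, "control"))
  tss <- vapply(seq_len(n), function(i) {
    pred <- res$at_risk[, i]
    sens <- mean(pred[cells])
    spec <- mean(!pred[background])
    sens + spec - 1
  }, numeric(1))
  out <- data.frame(variant_id = seq_len(n), design$matrix,
                    tss = tss,
                    fraction_area_at_risk = res$fraction_at_risk)
  class(out) <- c("variant_results", "data.frame")
  attr(out, "params") <- design$params
  out
}

#' Permutation variable importance of the varied traits
#'
#' Fits a bagged regression-tree ensemble (a random forest, 500 trees) of
#' TSS on the parameter columns and returns the permutation importance,
#' clamped to be nonnegative and normalized to sum to 1.
#'
#' @param results a `variant_results` data.frame.
#' @param seed integer seed for the forest.
#' @param ntree ensemble size.
#' @return Named numeric vector of importances summing to 1.
#' @export
variable_importance <- function(results, seed = 1L, ntree = 500) {
  params <- attr(results, "params")
  x <- results[, params, drop = FALSE]
  keep <- vapply(x, function(col) diff(range(col)) > 0, logical(1))
  imp <- stats::setNames(numeric(length(params)), params)
  if (any(keep) && diff(range(results$tss)) > 0) {
    rf <- with_seed(seed, randomForest::randomForest(
      x = x[, keep, drop = FALSE], y = results$tss,
      ntree = ntree, importance = TRUE))
    raw <- randomForest::importance(rf, type = 1)
    imp[rownames(raw)] <- pmax(raw[, 1], 0)
  }
  if (sum(imp) <= 0) imp[] <- 1 / length(imp) else imp <- imp / sum(imp)
  imp
}

#' Trim parameter ranges towards the well-performing variants
#'
#' For every parameter with variable importance above the cutoff, the new
#' range is the envelope of its values among variants with TSS above the
#' threshold; other parameters keep their range. If no variant passes, the
#' ranges are returned unchanged with a no-progress flag.
#'
#' @param results a `variant_results` data.frame.
#' @param importances named importances as from [variable_importance()].
#' @param ranges the ranges the design was drawn from.
#' @param tss_min TSS acceptance threshold (default 0.3).
#' @param importance_min importance cutoff (default 0.05).
#' @return A list with `ranges` and the logical `no_progress`.
#' @export
trim_ranges <- function(results, importances, ranges,
                        tss_min = 0.3, importance_min = 0.05) {
  if (nrow(results) < 1) stop("no results to trim from")
  pass <- results$tss > tss_min
  if (!any(pass)) return(list(ranges = ranges, no_progress = TRUE))
  new_ranges <- ranges
  for (nm in names(ranges)) {
    if (!is.na(importances[nm]) && importances[nm] > importance_min) {
      vals <- results[pass, nm]
      new_ranges[[nm]] <- c(min(vals), max(vals))
    }
  }
  list(ranges = new_ranges, no_progress = FALSE)
}

#' Iterative Latin-Hypercube sensitivity workflow
#'
#' Repeats design -> evaluation -> random-forest importance -> range
#' trimming until the largest relative range reduction across parameters
#' falls below the stopping fraction (or no variant passes the TSS
#' threshold). Ranges are nested across iterations by construction.
#'
#' @param ranges initial named ranges.
#' @param traits base `bird_traits`.
#' @param landscape a `tr_landscape`.
#' @param occurrences occurrences (data.frame or cell indices).
#' @param background background cells; default all.
#' @param seed integer seed.
#' @param n variants per iteration (default 1000).
#' @param tss_min,importance_min acceptance thresholds (0.3, 0.05).
#' @param stop_fraction relative range-reduction stopping rule (0.05).
#' @param max_iter safety cap on iterations.
#' @param control a [tr_control()] list.
#' @return A list of class `lhs_iteration`: final `ranges`, `iterations`,
#'   `no_progress`, a per-iteration `trace` data.frame (importances and
#'   range widths), and the last iteration's `results`.
#' @export
iterate_sensitivity <- function(ranges, traits, landscape, occurrences,
                                background = NULL, seed = 1L, n = 1000,
                                tss_min = 0.3, importance_min = 0.05,
                                stop_fraction = 0.05, max_iter = 10,
                                control = tr_control()) {
  env <- microclimate_grid(landscape, traits$animal_height_m, control)
  trace <- list()
  no_progress <- FALSE
  results <- NULL
  for (it in seq_len(max_iter)) {
    design <- lhs_sample(ranges, n, seed + it - 1L)
    results <- evaluate_variants(design, traits, landscape, occurrences,
                                 background, control, env = env)
    imp <- variable_importance(results, seed = seed + 1000L + it)
    tr <- trim_ranges(results, imp, ranges, tss_min, importance_min)
    old_w <- vapply(ranges, diff, numeric(1))
    new_w <- vapply(tr$ranges, diff, numeric(1))
    reduction <- ifelse(old_w > 0, 1 - new_w / old_w, 0)
    trace[[it]] <- data.frame(iteration = it, parameter = names(ranges),
                              importance = unname(imp[names(ranges)]),
                              width = unname(new_w),
                              reduction = unname(reduction))
    ranges <- tr$ranges
    if (tr$no_progress) { no_progress <- TRUE; break }
    if (max(reduction) < stop_fraction) break
  }
  structure(list(ranges = ranges, iterations = length(trace),
                 no_progress = no_progress,
                 trace = do.call(rbind, trace), results = results),
            class = "lhs_iteration")
}

#' Per-pixel intraspecific ensemble map
#'
#' Runs every variant of a (default 100-variant) design over the landscape
#' and assigns to each pixel the lowest BMR-normalized energy requirement
#' among the variants; a pixel is at risk when at least one variant
#' classifies it so (the minimal-energy reading: the ensemble at-risk set
#' is the union of the per-variant sets).
#'
#' @param design an [lhs_sample()] design (default size 100).
#' @param traits base `bird_traits`.
#' @param landscape a `tr_landscape`.
#' @param control a [tr_control()] list.
#' @return A list of class `intraspecific_map`: logical `at_risk` matrix,
#'   `min_multiple` matrix (per-cell minimum over variants of the worst
#'   monthly multiple), `fraction_at_risk`, and `n_variants`.
#' @export
intraspecific_map <- function(design, traits, landscape,
                              control = tr_control()) {
  env <- microclimate_grid(landscape, traits$animal_height_m, control)
  n <- nrow(design$matrix)
  variants <- lapply(seq_len(n), function(i)
    apply_variant(traits, design$matrix[i, ], control))
  res <- grid_energetics(env,
                         lapply(variants, `[[`, "traits"),
                         lapply(variants, `[[`, "control"))
  nr <- landscape$grid_rows; nc <- landscape$grid_cols
  at_risk <- matrix(apply(res$at_risk, 1, any), nr, nc)
  min_mult <- matrix(apply(res$max_monthly_multiple, 1, min), nr, nc)
  structure(list(at_risk = at_risk, min_multiple = min_mult,
                 fraction_at_risk = mean(at_risk), n_variants = n,
                 per_variant_at_risk = res$at_risk,
                 per_variant_multiple = res$max_monthly_multiple),
            class = "intraspecific_map")
}
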