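test_that("Latin designs stratify every parameter exactly", {
  rng <- list(a = c(0, 10), b = c(-5, 5), c = c(100, 101))
  d <- lhs_sample(rng, n = 10, seed = 3)
  for (j in seq_along(rng)) {
    lo <- rng[[j]][1]; hi <- rng[[j]][2]
    stratum <- floor((d$matrix[, j] - lo) / (hi - lo) * 10)
    stratum[stratum == 10] <- 9
    expect_setequal(stratum, 0:9)    # each decile exactly once
  }
  single <- lhs_sample(rng, n = 1, seed = 1)
  expect_true(all(single$matrix >= c(0, -5, 100) &
                    single$matrix <= c(10, 5, 101)))
  expect_equal(formals(lhs_sample)$n, 1000)  # species-level default
  expect_error(lhs_sample(list(a = c(2, 1)), 5, 1), "inverted")
  expect_error(lhs_sample(list(), 5, 1))
})

test_that("variant application rescales geometry and plumage with mass", {
  sp <- parakeet()
  v <- apply_variant(sp, c(mass_kg = 8 * sp$mass_kg))
  expect_equal(v$traits$parts$torso$semi_axes_m / sp$parts$torso$semi_axes_m,
               rep(2, 3))
  expect_equal(v$traits$parts$torso$feather_depth_dorsal_m /
                 sp$parts$torso$feather_depth_dorsal_m, 2)
  v2 <- apply_variant(sp, c(core_skin_dt_c = 2, delta_exhale_c = 8))
  expect_equal(v2$control$core_skin_dt_c, 2)
  expect_equal(v2$control$delta_exhale_c, 8)
  expect_equal(v2$traits$mass_kg, sp$mass_kg)
})

test_that("variant evaluation is pure and consistent with single maps", {
  w <- oracle_world()
  sp <- parakeet(); ctl <- oracle_control()
  occ <- sample_occurrences(w$truth, w$landscape, 60, 0, seed = 8)
  rng <- default_trait_ranges(sp)
  d <- lhs_sample(rng, 6, seed = 2)
  # duplicated rows give identical results
  d$matrix <- d$matrix[c(1:3, 1:3), ]
  res <- evaluate_variants(d, sp, w$landscape, occ, control = ctl)
  expect_equal(res$tss[1:3], res$tss[4:6])
  expect_equal(res$fraction_area_at_risk[1:3],
               res$fraction_area_at_risk[4:6])
  expect_true(all(res$tss >= -1 & res$tss <= 1))
  # TSS recomputed from the variant's own map matches
  v1 <- apply_variant(sp, d$matrix[1, ], ctl)
  map1 <- map_species(v1$traits, w$landscape, v1$control)
  cells <- attr(occ, "cell")
  pred <- as.vector(map1$at_risk)
  sens <- mean(pred[cells])
  spec <- mean(!pred)
  expect_equal(res$tss[1], sens + spec - 1, tolerance = 1e-12)
  expect_equal(res$fraction_area_at_risk[1], map1$fraction_at_risk)
})

test_that("range trimming follows the TSS and importance rules", {
  params <- c("a", "b")
  res <- data.frame(variant_id = 1:6, a = c(2, 2.5, 3, 7, 8, 9),
                    b = c(1, 2, 3, 4, 5, 6),
                    tss = c(0.5, 0.4, 0.35, 0.1, 0.05, 0),
                    fraction_area_at_risk = 0.5)
  attr(res, "params") <- params
  ranges <- list(a = c(0, 10), b = c(0, 10))
  imp <- c(a = 0.9, b = 0.01)
  tr <- trim_ranges(res, imp, ranges)
  expect_equal(tr$ranges$a, c(2, 3))   # envelope of the passing variants
  expect_equal(tr$ranges$b, c(0, 10))  # unimportant parameter untouched
  expect_false(tr$no_progress)
  # nothing passes: unchanged ranges and the no-progress flag
  res$tss <- res$tss - 1
  tr2 <- trim_ranges(res, imp, ranges)
  expect_identical(tr2$ranges, ranges)
  expect_true(tr2$no_progress)
})

test_that("iteration terminates on degenerate ranges and nests ranges", {
  w <- oracle_world()
  sp <- parakeet(); ctl <- oracle_control()
  occ <- sample_occurrences(w$truth, w$landscape, 50, 0, seed = 4)
  rng <- default_trait_ranges(sp)
  degenerate <- lapply(rng, function(r) rep(mean(r), 2))
  it <- iterate_sensitivity(degenerate, sp, w$landscape, occ, seed = 5,
                            n = 20, control = ctl)
  expect_equal(it$iterations, 1)
  # a live run: every later range nested in the initial one
  rng2 <- rng
  for (nm in names(rng2)) if (nm != "core_temp_c")
    rng2[[nm]] <- rep(mean(rng2[[nm]]), 2)
  rng2$core_temp_c <- c(38, 44)
  it2 <- iterate_sensitivity(rng2, sp, w$landscape, occ, seed = 6,
                             n = 120, control = ctl, max_iter = 4)
  expect_true(it2$ranges$core_temp_c[1] >= 38 - 1e-9)
  expect_true(it2$ranges$core_temp_c[2] <= 44 + 1e-9)
  widths <- subset(it2$trace, parameter == "core_temp_c")$width
  expect_true(all(diff(widths) <= 1e-9))
})

test_that("the intraspecific ensemble is the union of its variants", {
  w <- oracle_world()
  sp <- parakeet(); ctl <- oracle_control()
  d <- lhs_sample(default_trait_ranges(sp), 12, seed = 9)
  ens <- intraspecific_map(d, sp, w$landscape, ctl)
  env <- microclimate_grid(w$landscape, sp$animal_height_m, ctl)
  # brute-force union oracle: run each variant as its own species map
  union <- matrix(FALSE, w$landscape$grid_rows, w$landscape$grid_cols)
  mins <- matrix(Inf, w$landscape$grid_rows, w$landscape$grid_cols)
  for (i in seq_len(12)) {
    v <- apply_variant(sp, d$matrix[i, ], ctl)
    mp <- map_species(v$traits, w$landscape, v$control, env = env)
    union <- union | mp$at_risk
    mins <- pmin(mins, mp$max_monthly_multiple)
    expect_true(all(ens$min_multiple <= mp$max_monthly_multiple + 1e-12))
  }
  expect_identical(ens$at_risk, union)
  expect_equal(ens$min_multiple, mins, tolerance = 1e-12)
  # a single-variant design reduces to that variant's species map
  d1 <- d; d1$matrix <- d$matrix[1, , drop = FALSE]
  ens1 <- intraspecific_map(d1, sp, w$landscape, ctl)
  v1 <- apply_variant(sp, d$matrix[1, ], ctl)
  mp1 <- map_species(v1$traits, w$landscape, v1$control)
  expect_identical(ens1$at_risk, mp1$at_risk)
})

test_that("ensemble at-risk area contains the species-level area when the
           species vector is among the variants", {
  w <- oracle_world()
  sp <- parakeet(); ctl <- oracle_control()
  d <- lhs_sample(default_trait_ranges(sp), 8, seed = 10)
  base_row <- c(bmr_w = sp$bmr_w, activity_multiplier = sp$activity_multiplier,
                mass_kg = sp$mass_kg,
                body_density_kg_m3 = sp$body_density_kg_m3,
                fat_fraction = sp$fat_fraction,
                core_temp_c = sp$core_temp_c, core_skin_dt_c = 0,
                feather_diameter_m = sp$feather_diameter_m,
                feather_length_scale = 1, feather_depth_scale = 1,
                reflectivity_scale = 1, delta_exhale_c = 5)
  d$matrix[1, ] <- base_row[colnames(d$matrix)]
  ens <- intraspecific_map(d, sp, w$landscape, ctl)
  base_map <- map_species(sp, w$landscape, ctl)
  expect_true(all(ens$at_risk >= base_map$at_risk))
})
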