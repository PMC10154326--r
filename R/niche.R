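#' Principal-component climate space
#'
#' Centered, scaled PCA of the pooled background climates (native plus
#' invaded areas); the first two axes define the environmental space all
#' niche metrics work in. Sign convention: within each of the two axes
#' the loading of largest magnitude is made positive, so the
#' decomposition is deterministic.
#'
#' @param background numeric matrix/data.frame, observations x variables
#'   (>= 3 observations, >= 2 variables).
#' @return A list of class `env_pca`: `scores` (n x 2), `loadings`
#'   (variables x 2), `explained` (fraction of variance per axis),
#'   `center`, `scale`.
#' @export
env_pca <- function(background) {
  x <- as.matrix(background)
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 observations, >= 2 variables")
  sdev <- apply(x, 2, stats::sd)
  if (sum(sdev > 0) < 2) stop("rank < 2: fewer than two varying variables")
  pc <- stats::prcomp(x[, sdev > 0, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  if (ncol(pc$rotation) < 2) stop("rank < 2")
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = rot, explained = expl[1:2],
                 center = pc$center, scale = pc$scale,
                 keep = which(sdev > 0)),
            class = "env_pca")
}

#' Project new climates onto a fitted PCA space
#' @param pca an [env_pca()] fit.
#' @param x new observations x variables matrix (same variables).
#' @return n x 2 score matrix.
#' @export
project_pca <- function(pca, x) {
  x <- as.matrix(x)[, pca$keep, drop = FALSE]
  scale(x, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Kernel-smoothed occurrence density over environmental space
#'
#' Projects occurrence and background scores onto an R x R grid bounded by
#' the background extent, and smooths both with a Gaussian kernel whose
#' per-axis bandwidth follows the normal-reference plug-in rule. The
#' occurrence density is normalized to sum to 1.
#'
#' @param scores_background background score matrix (n x 2).
#' @param scores_occurrences occurrence score matrix (>= 5 rows, the
#'   minimum for niche-dynamics analyses); points outside the background
#'   bounds are clipped onto them with a warning.
#' @param R grid resolution per axis (default 100).
#' @param bounds optional list `(x, y)` of axis limits, e.g. to share
#'   bounds across ranges.
#' @return A list of class `niche_density`: matrices `z` (occurrence,
#'   sums to 1), `z_env` (availability, sums to 1), `z_cor` (occupancy
#'   corrected for availability, sums to 1), axes `x`, `y`, and the
#'   75th-percentile availability mask `env75`.
#' @export
density_grid <- function(scores_background, scores_occurrences, R = 100,
                         bounds = NULL) {
  bg <- as.matrix(scores_background)
  oc <- as.matrix(scores_occurrences)
  if (nrow(oc) < 5) stop("at least five occurrence locations are required")
  if (is.null(bounds)) {
    bounds <- list(x = range(bg[, 1]), y = range(bg[, 2]))
  }
  clip <- oc[, 1] < bounds$x[1] | oc[, 1] > bounds$x[2] |
    oc[, 2] < bounds$y[1] | oc[, 2] > bounds$y[2]
  if (any(clip)) {
    warning(sum(clip), " occurrences outside background bounds were clipped")
    oc[, 1] <- pmin(pmax(oc[, 1], bounds$x[1]), bounds$x[2])
    oc[, 2] <- pmin(pmax(oc[, 2], bounds$y[1]), bounds$y[2])
  }
  bw <- function(v, lim) {
    b <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
    if (!is.finite(b) || b <= 0) b <- diff(lim) / 10
    b
  }
  kd <- function(pts) {
    MASS::kde2d(pts[, 1], pts[, 2], n = R,
                h = c(bw(pts[, 1], bounds$x), bw(pts[, 2], bounds$y)),
                lims = c(bounds$x, bounds$y))
  }
  zo <- kd(oc); zb <- kd(bg)
  z <- zo$z / sum(zo$z)
  z_env <- zb$z / sum(zb$z)
  zc <- ifelse(z_env > 0, z / z_env, 0)
  if (sum(zc) > 0) zc <- zc / sum(zc)
  structure(list(z = z, z_env = z_env, z_cor = zc,
                 x = zo$x, y = zo$y,
                 env75 = mass_region(z_env, 0.75)),
            class = "niche_density")
}

# smallest set of cells capturing `mass` of the density (by descending
# density)
mass_region <- function(z, mass) {
  o <- order(z, decreasing = TRUE)
  cs <- cumsum(z[o]) / sum(z)
  keep <- o[seq_len(which(cs >= mass)[1])]
  out <- matrix(FALSE, nrow(z), ncol(z))
  out[keep] <- TRUE
  out
}

# cells counted as occupied: those carrying 95% of the occurrence density
occupied_region <- function(density, mass = 0.95) {
  mass_region(density$z, mass)
}

#' Niche expansion, stability and unfilling
#'
#' Computed on the environmental space shared between both ranges: the
#' analysis mask is the intersection of each range's 75th-percentile
#' available-climate region. Occupied cells are those carrying 95% of a
#' range's occurrence density. Expansion is the share of the invasive
#' occupied density (within the mask) sitting in cells outside the native
#' occupied region; stability is its complement; unfilling is the share
#' of the native occupied density (within the mask) outside the invasive
#' occupied region.
#'
#' @param native,invasive `niche_density` grids on shared bounds.
#' @param quantile availability quantile defining each range's analysed
#'   climates (default 0.75).
#' @param occupied_mass density mass defining occupancy (default 0.95).
#' @return A list of class `niche_metrics`: `expansion`, `stability`,
#'   `unfilling`, all in `[0, 1]` with `expansion + stability = 1`.
#' @export
niche_esu <- function(native, invasive, quantile = 0.75,
                      occupied_mass = 0.95) {
  if (!identical(dim(native$z), dim(invasive$z)))
    stop("grids must share bounds")
  mask <- mass_region(native$z_env, quantile) &
    mass_region(invasive$z_env, quantile)
  if (!any(mask)) stop("empty shared-climate mask")
  occ_nat <- mass_region(native$z, occupied_mass)
  occ_inv <- mass_region(invasive$z, occupied_mass)
  zi <- invasive$z * (mask & occ_inv)
  zn <- native$z * (mask & occ_nat)
  if (sum(zi) == 0 || sum(zn) == 0) stop("no density inside the mask")
  expansion <- sum(zi[!occ_nat]) / sum(zi)
  unfilling <- sum(zn[!occ_inv]) / sum(zn)
  structure(list(expansion = expansion, stability = 1 - expansion,
                 unfilling = unfilling),
            class = "niche_metrics")
}

#' @export
print.niche_metrics <- function(x, ...) {
  cat(sprintf("niche dynamics: expansion %.3f, stability %.3f, unfilling %.3f\n",
              x$expansion, x$stability, x$unfilling))
  invisible(x)
}

#' Schoener's D overlap between two niche densities
#'
#' `D = 1 - 0.5 * sum |z1 - z2|` over availability-corrected,
#' sum-normalized densities.
#'
#' @param d1,d2 `niche_density` grids on shared bounds (or plain matrices
#'   that already sum to 1).
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(d1, d2) {
  z1 <- if (inherits(d1, "niche_density")) d1$z_cor else d1 / sum(d1)
  z2 <- if (inherits(d2, "niche_density")) d2$z_cor else d2 / sum(d2)
  1 - 0.5 * sum(abs(z1 - z2))
}

#' Niche equivalency and similarity randomization tests
#'
#' The observed statistic is Schoener's D between the two ranges'
#' availability-corrected densities. The equivalency null pools both
#' ranges' occurrences and resplits them at random at the original sample
#' sizes; its p-value is the fraction of null runs with D at or below the
#' observed (low p: niches are less equivalent than random splits). The
#' similarity null redraws one range's occurrences at random from its
#' background; its p-value is the fraction of null runs with D at or
#' above the observed (low p: niches are more similar than expected from
#' the available climates).
#'
#' @param native_bg,invasive_bg background score matrices (n x 2).
#' @param native_occ,invasive_occ occurrence score matrices.
#' @param mode `"equivalency"` or `"similarity"`.
#' @param n_reps number of randomizations (>= 99).
#' @param seed integer seed.
#' @param R grid resolution (default 100).
#' @return A list of class `niche_test`: `d_observed`, `p_value`,
#'   `null_d`, `mode`.
#' @export
niche_randomization_test <- function(native_bg, invasive_bg,
                                     native_occ, invasive_occ,
                                     mode = c("equivalency", "similarity"),
                                     n_reps = 99, seed = 1L, R = 100) {
  mode <- match.arg(mode)
  if (n_reps < 99) stop("n_reps must be >= 99")
  if (nrow(native_occ) < 5 || nrow(invasive_occ) < 5)
    stop("at least five occurrences per range are required")
  all_bg <- rbind(as.matrix(native_bg), as.matrix(invasive_bg))
  bounds <- list(x = range(all_bg[, 1]), y = range(all_bg[, 2]))
  dn <- density_grid(native_bg, native_occ, R, bounds)
  di <- density_grid(invasive_bg, invasive_occ, R, bounds)
  d_obs <- schoener_d(dn, di)
  n1 <- nrow(native_occ); n2 <- nrow(invasive_occ)
  pool <- rbind(as.matrix(native_occ), as.matrix(invasive_occ))
  null_d <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    if (mode == "equivalency") {
      idx <- sample(n1 + n2, n1)
      o1 <- pool[idx, , drop = FALSE]
      o2 <- pool[-idx, , drop = FALSE]
      schoener_d(density_grid(native_bg, o1, R, bounds),
                 density_grid(invasive_bg, o2, R, bounds))
    } else {
      ridx <- sample(nrow(invasive_bg), n2, replace = TRUE)
      o2 <- as.matrix(invasive_bg)[ridx, , drop = FALSE]
      schoener_d(dn, density_grid(invasive_bg, o2, R, bounds))
    }
  }, numeric(1)))
  p <- if (mode == "equivalency") {
    (1 + sum(null_d <= d_obs)) / (1 + n_reps)
  } else {
    (1 + sum(null_d >= d_obs)) / (1 + n_reps)
  }
  structure(list(d_observed = d_obs, p_value = p, null_d = null_d,
                 mode = mode), class = "niche_test")
}

#' Potential Niche Truncation Index
#'
#' Fraction of the occupied niche region's boundary cells that abut or
#' exceed the margin of the available climate space: a boundary cell
#' counts as truncated when it lies outside the available region, touches
#' a non-available neighbour (4-neighbourhood), or sits on the grid edge.
#' 0 when the occupied region is strictly interior to the available
#' space.
#'
#' @param occupied logical matrix of occupied cells, or a `niche_density`
#'   (its 95%-mass occurrence region is used).
#' @param available logical matrix of available cells, or a
#'   `niche_density` (its positive-availability region is used).
#' @return Index in `[0, 1]`.
#' @export
pnti <- function(occupied, available) {
  occ <- if (inherits(occupied, "niche_density"))
    occupied_region(occupied) else occupied
  avail <- if (inherits(available, "niche_density"))
    available$z_env > 1e-12 else available
  if (!any(occ)) stop("empty occupied region")
  nr <- nrow(occ); nc <- ncol(occ)
  pad <- function(m, fill) {
    out <- matrix(fill, nr + 2, nc + 2)
    out[2:(nr + 1), 2:(nc + 1)] <- m
    out
  }
  po <- pad(occ, FALSE)
  pa <- pad(avail, FALSE)
  boundary <- 0L; truncated <- 0L
  for (i in 2:(nr + 1)) for (j in 2:(nc + 1)) {
    if (!po[i, j]) next
    nb_occ <- c(po[i - 1, j], po[i + 1, j], po[i, j - 1], po[i, j + 1])
    if (all(nb_occ)) next           # interior of the occupied region
    boundary <- boundary + 1L
    nb_av <- c(pa[i - 1, j], pa[i + 1, j], pa[i, j - 1], pa[i, j + 1])
    if (!pa[i, j] || !all(nb_av)) truncated <- truncated + 1L
  }
  if (boundary == 0L) return(0)
  truncated / boundary
}
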