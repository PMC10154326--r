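#' Great-circle distance between two points
#'
#' Haversine distance with the mean Earth radius 6371.0088 km.
#'
#' @param p1,p2 numeric `c(lon, lat)` in decimal degrees, or two-column
#'   matrices.
#' @return Distance in km.
#' @export
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371008.8) / 1000
}

#' Spatially thin occurrence records
#'
#' Greedy rarefaction in a seeded random order: each point is kept iff it
#' lies at least `min_km` from every already-kept point, so all pairwise
#' distances in the output meet the minimum. The customary radii are
#' 50 km (default) and 10 km (dense invasive ranges).
#'
#' @param points data.frame with `lon`, `lat` (other columns carried
#'   through).
#' @param min_km minimum pairwise distance (km, > 0).
#' @param seed integer seed fixing the scan order (retained counts depend
#'   on order).
#' @return The retained subset of `points`, with attribute `seed`.
#' @export
thin_occurrences <- function(points, min_km = 50, seed = 1L) {
  if (min_km <= 0) stop("min_km must be positive")
  n <- nrow(points)
  if (n <= 1) return(points)
  ord <- with_seed(seed, sample(n))
  keep <- integer(0)
  coords <- as.matrix(points[, c("lon", "lat")])
  for (i in ord) {
    if (length(keep) == 0 ||
        all(haversine_km(coords[keep, , drop = FALSE],
                         coords[i, , drop = FALSE]) >= min_km)) {
      keep <- c(keep, i)
    }
  }
  out <- points[sort(keep), , drop = FALSE]
  attr(out, "seed") <- seed
  out
}

#' Background radius from occurrence geometry
#'
#' The mean over all unordered pairs of great-circle distances between
#' occurrences; used as the buffer radius delimiting the accessible
#' background.
#'
#' @param points data.frame or matrix with `lon`, `lat` (>= 2 rows).
#' @return Radius in km.
#' @export
background_radius <- function(points) {
  coords <- as.matrix(points[, c("lon", "lat")])
  n <- nrow(coords)
  if (n < 2) stop("need at least two points")
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) {
    d <- haversine_km(coords[i, , drop = FALSE],
                      coords[(i + 1):n, , drop = FALSE])
    tot <- tot + sum(d); cnt <- cnt + length(d)
  }
  tot / cnt
}

#' Omission-rate threshold on training presence scores
#'
#' The threshold is the `rate` quantile of the presence scores with the
#' lower (type 1) interpolation convention, so that at most `rate` of the
#' training presences score below it. Supported rates follow the 2.5%
#' and 5% training-omission conventions; any rate in `[0, 1)` is
#' accepted.
#'
#' @param scores numeric suitability scores at training presences.
#' @param rate omission rate (default 0.05).
#' @return The threshold value.
#' @export
omission_threshold <- function(scores, rate = 0.05) {
  if (length(scores) == 0) stop("empty scores")
  if (rate < 0 || rate >= 1) stop("rate must be in [0,1)")
  if (rate == 0) return(min(scores))
  unname(stats::quantile(scores, rate, type = 1))
}

#' Confusion-matrix evaluation of a binary forecast
#'
#' @param pred_at_risk logical predictions.
#' @param labels logical (or 0/1) observed presence labels; both classes
#'   must be present.
#' @return A list of class `eval_result`: `sensitivity` (correctly
#'   predicted presences), `specificity` (correctly identified
#'   absences/background), `tss = sensitivity + specificity - 1`.
#' @export
confusion_metrics <- function(pred_at_risk, labels) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) stop("both classes must be present")
  sens <- mean(pred_at_risk[labels])
  spec <- mean(!pred_at_risk[!labels])
  structure(list(sensitivity = sens, specificity = spec,
                 tss = sens + spec - 1),
            class = "eval_result")
}

#' Partial ROC with bootstrap
#'
#' Partial area under the ROC curve restricted to omission rates at most
#' `E`, expressed as the ratio of the model's partial AUC to that of the
#' random (diagonal) classifier on the same sensitivity band. Each
#' bootstrap iteration resamples 50% of the test presences; the p-value
#' is the fraction of iterations with ratio at or below 1.
#'
#' For binary-in-origin mechanistic maps, use the continuous score
#' `-max_monthly_multiple` (a lower requirement means more suitable).
#'
#' @param scores_surface suitability scores of all cells (the prediction
#'   surface).
#' @param presence_scores suitability scores at the test presences
#'   (>= 10).
#' @param E acceptable omission rate (0.025 or 0.05; default 0.05).
#' @param iterations bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return A list of class `partial_roc`: `auc_ratio` (mean over
#'   iterations), `p_value`, `ratios`.
#' @export
partial_roc <- function(scores_surface, presence_scores, E = 0.05,
                        iterations = 1000, seed = 1L) {
  if (length(presence_scores) < 10) stop("need >= 10 test presences")
  if (diff(range(scores_surface)) == 0)
    stop("degenerate (constant) score surface")
  # threshold sweep over the surface's quantiles
  th <- unique(stats::quantile(scores_surface, probs = seq(0, 1, 0.01),
                               names = FALSE, type = 7))
  frac_area <- vapply(th, function(t) mean(scores_surface >= t), numeric(1))
  one_ratio <- function(pres) {
    sens <- vapply(th, function(t) mean(pres >= t), numeric(1))
    keep <- sens >= 1 - E
    if (sum(keep) < 2) return(NA_real_)
    x <- frac_area[keep]; y <- sens[keep]
    o <- order(x)
    x <- x[o]; y <- y[o]
    auc_mod <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    auc_null <- sum(diff(x) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
    if (auc_null <= 0) return(NA_real_)
    auc_mod / auc_null
  }
  n <- length(presence_scores)
  ratios <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    one_ratio(presence_scores[sample(n, max(1, floor(n / 2)),
                                     replace = TRUE)])
  }, numeric(1)))
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) stop("partial ROC undefined for these inputs")
  structure(list(auc_ratio = mean(ratios),
                 p_value = mean(ratios <= 1),
                 ratios = ratios),
            class = "partial_roc")
}

#' Mobility-Oriented Parity extrapolation diagnostic
#'
#' Flags projection points of strict extrapolation (any variable outside
#' the calibration min-max) and scores environmental similarity as
#' `1 - d / max(d)`, where `d` is the mean Euclidean distance (on
#' calibration-standardized variables) to the nearest `reference_fraction`
#' of calibration points.
#'
#' @param calibration_climates calibration matrix (points x variables).
#' @param projection_climates projection matrix (same variables).
#' @param reference_fraction fraction of nearest calibration points
#'   averaged (default 0.1).
#' @return A list of class `mop_result`: `similarity` in `[0, 1]`,
#'   logical `strict_extrapolation`, and `mean_distance`.
#' @export
mop_mask <- function(calibration_climates, projection_climates,
                     reference_fraction = 0.1) {
  cal <- as.matrix(calibration_climates)
  proj <- as.matrix(projection_climates)
  if (ncol(cal) != ncol(proj)) stop("variable mismatch")
  lo <- apply(cal, 2, min); hi <- apply(cal, 2, max)
  strict <- apply(proj, 1, function(p) any(p < lo | p > hi))
  mu <- colMeans(cal)
  sdv <- apply(cal, 2, stats::sd); sdv[sdv == 0] <- 1
  cs <- scale(cal, mu, sdv); ps <- scale(proj, mu, sdv)
  k <- max(1L, ceiling(reference_fraction * nrow(cal)))
  d <- vapply(seq_len(nrow(ps)), function(i) {
    di <- sqrt(colSums((t(cs) - ps[i, ])^2))
    mean(sort(di)[seq_len(k)])
  }, numeric(1))
  sim <- if (max(d) > 0) 1 - d / max(d) else rep(1, length(d))
  structure(list(similarity = sim, strict_extrapolation = strict,
                 mean_distance = d),
            class = "mop_result")
}

#' Evaluate a forecast with an optional extrapolation mask
#'
#' Confusion metrics restricted to cells outside strict extrapolation;
#' with an empty mask the result equals the unmasked statistics.
#'
#' @param pred_at_risk logical predictions per cell.
#' @param labels logical presence labels per cell.
#' @param strict_extrapolation optional logical mask of cells to exclude.
#' @return An `eval_result`.
#' @export
confusion_metrics_masked <- function(pred_at_risk, labels,
                                     strict_extrapolation = NULL) {
  if (is.null(strict_extrapolation))
    return(confusion_metrics(pred_at_risk, labels))
  keep <- !strict_extrapolation
  confusion_metrics(pred_at_risk[keep], labels[keep])
}
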