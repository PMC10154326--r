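test_that("PCA climate space is deterministic and well-normalized", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4)
  p <- env_pca(x)
  expect_equal(dim(p$scores), c(50, 2))
  # sign convention: dominant loading positive on both axes
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # two perfectly correlated variables: one axis carries all variance
  y <- cbind(a = 1:20, b = 2 * (1:20) + 3)
  expect_equal(env_pca(y)$explained[1], 1, tolerance = 1e-12)
  # flipping a variable's sign leaves explained variance unchanged
  x2 <- x; x2[, 2] <- -x2[, 2]
  expect_equal(env_pca(x2)$explained, p$explained, tolerance = 1e-12)
  expect_error(env_pca(matrix(1, 5, 2)), "rank")
  expect_error(env_pca(x[1:2, ]))
})

test_that("PCA scores match a hand eigen-decomposition on a 4x2 example", {
  x <- matrix(c(1, 2, 3, 6, 2, 1, 5, 4), ncol = 2)
  p <- env_pca(x)
  xs <- scale(x)
  ev <- eigen(stats::cov(xs))
  hand <- xs %*% ev$vectors
  # same up to per-axis sign
  for (j in 1:2) {
    expect_true(max(abs(p$scores[, j] - hand[, j])) < 1e-9 ||
                  max(abs(p$scores[, j] + hand[, j])) < 1e-9)
  }
  expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-12)
})

test_that("density grids normalize, localize and flatten as expected", {
  set.seed(2)
  bg <- matrix(runif(4000, -1, 1), ncol = 2)
  occ <- matrix(rnorm(60, 0.5, 0.03), ncol = 2)
  d <- density_grid(bg, occ, R = 50)
  expect_equal(sum(d$z), 1, tolerance = 1e-9)
  expect_equal(sum(d$z_env), 1, tolerance = 1e-9)
  # density mode lands at the cluster
  peak <- which(d$z == max(d$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(d$x[peak[1]] - 0.5), 0.15)
  expect_lt(abs(d$y[peak[2]] - 0.5), 0.15)
  # uniform occurrences over the background: corrected ratio roughly flat
  occ_u <- bg[sample(nrow(bg), 1000), ]
  du <- density_grid(bg, occ_u, R = 30)
  core <- du$z_env > stats::quantile(du$z_env, 0.6)
  ratio <- du$z[core] / du$z_env[core]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.25)
  expect_error(density_grid(bg, occ[1:4, , drop = FALSE]), "five")
  expect_warning(density_grid(bg, matrix(c(5, 5, 0.1, 0.1, 0, 0, 0.2, 0.2,
                                           0.3, 0.3), ncol = 2,
                                         byrow = TRUE)), "clipped")
})

test_that("expansion/stability/unfilling identities hold", {
  set.seed(3)
  bg <- matrix(runif(4000, -1, 1), ncol = 2)
  occ <- matrix(rnorm(80, 0, 0.2), ncol = 2)
  d <- density_grid(bg, occ, R = 40)
  m <- niche_esu(d, d)
  expect_equal(m$expansion, 0)
  expect_equal(m$stability, 1)
  expect_equal(m$unfilling, 0)
  # disjoint clusters: full expansion and unfilling
  occ_a <- matrix(rnorm(80, -0.6, 0.03), ncol = 2)
  occ_b <- matrix(rnorm(80, 0.6, 0.03), ncol = 2)
  da <- density_grid(bg, occ_a, R = 40)
  db <- density_grid(bg, occ_b, R = 40)
  m2 <- niche_esu(da, db)
  expect_gt(m2$expansion, 0.95)
  expect_gt(m2$unfilling, 0.95)
  expect_equal(m2$expansion + m2$stability, 1)
})

test_that("metrics match a brute-force sum on hand-built 10x10 grids", {
  hand_density <- function(z, z_env) {
    structure(list(z = z / sum(z), z_env = z_env / sum(z_env),
                   z_cor = NULL, x = 1:10, y = 1:10), class = "niche_density")
  }
  set.seed(4)
  z1 <- matrix(runif(100), 10); z2 <- matrix(runif(100), 10)
  e1 <- matrix(runif(100, 0.5, 1), 10); e2 <- matrix(runif(100, 0.5, 1), 10)
  dn <- hand_density(z1, e1); di <- hand_density(z2, e2)
  m <- niche_esu(dn, di)
  # independent cell-by-cell evaluation
  top_mass <- function(z, q) {
    o <- order(z, decreasing = TRUE)
    sel <- o[seq_len(which(cumsum(z[o]) / sum(z) >= q)[1])]
    grid <- matrix(FALSE, nrow(z), ncol(z)); grid[sel] <- TRUE; grid
  }
  mask <- top_mass(dn$z_env, 0.75) & top_mass(di$z_env, 0.75)
  occ_n <- top_mass(dn$z, 0.95); occ_i <- top_mass(di$z, 0.95)
  num_e <- 0; den_e <- 0; num_u <- 0; den_u <- 0
  for (i in 1:10) for (j in 1:10) {
    if (!mask[i, j]) next
    if (occ_i[i, j]) {
      den_e <- den_e + di$z[i, j]
      if (!occ_n[i, j]) num_e <- num_e + di$z[i, j]
    }
    if (occ_n[i, j]) {
      den_u <- den_u + dn$z[i, j]
      if (!occ_i[i, j]) num_u <- num_u + dn$z[i, j]
    }
  }
  expect_equal(m$expansion, num_e / den_e, tolerance = 1e-12)
  expect_equal(m$unfilling, num_u / den_u, tolerance = 1e-12)
  expect_equal(m$stability, 1 - num_e / den_e, tolerance = 1e-12)
})

test_that("Schoener's D equals its direct sum and the tests are seeded", {
  set.seed(5)
  z1 <- matrix(runif(64), 8); z1 <- z1 / sum(z1)
  z2 <- matrix(runif(64), 8); z2 <- z2 / sum(z2)
  expect_equal(schoener_d(z1, z2), 1 - 0.5 * sum(abs(z1 - z2)),
               tolerance = 1e-12)
  expect_equal(schoener_d(z1, z1), 1)
  bg <- matrix(runif(2000, -1, 1), ncol = 2)
  occ <- matrix(rnorm(60, 0, 0.3), ncol = 2)
  t1 <- niche_randomization_test(bg, bg, occ, occ, "equivalency",
                                 n_reps = 99, seed = 11, R = 30)
  t2 <- niche_randomization_test(bg, bg, occ, occ, "equivalency",
                                 n_reps = 99, seed = 11, R = 30)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$null_d, t2$null_d)
  # identical ranges: observed D is maximal, no significant difference
  expect_equal(t1$d_observed, 1, tolerance = 1e-9)
  expect_gt(t1$p_value, 0.5)
  t3 <- niche_randomization_test(bg, bg, occ, occ, "similarity",
                                 n_reps = 99, seed = 12, R = 30)
  expect_lt(t3$p_value, 0.5)   # a niche identical to itself is similar
})

test_that("potential niche truncation counts boundary abutment", {
  avail <- matrix(FALSE, 10, 10); avail[2:9, 2:9] <- TRUE
  inner <- matrix(FALSE, 10, 10); inner[4:6, 4:6] <- TRUE
  expect_equal(pnti(inner, avail), 0)
  expect_equal(pnti(avail, avail), 1)
  # hand-counted partial abutment: a 2-wide strip spanning the full
  # available height; all 16 cells are boundary cells and exactly the 4
  # in the top and bottom rows touch the available margin
  occ <- matrix(FALSE, 10, 10); occ[2:9, 4:5] <- TRUE
  expect_equal(pnti(occ, avail), 4 / 16)
  expect_error(pnti(matrix(FALSE, 3, 3), avail))
})

test_that("metrics are robust to grid resolution on smooth densities", {
  set.seed(6)
  bg <- matrix(runif(6000, -1, 1), ncol = 2)
  occ_n <- matrix(rnorm(150, -0.2, 0.25), ncol = 2)
  occ_i <- matrix(rnorm(150, 0.2, 0.25), ncol = 2)
  vals <- lapply(c(50, 100, 200), function(R) {
    dn <- density_grid(bg, occ_n, R)
    di <- density_grid(bg, occ_i, R)
    niche_esu(dn, di)
  })
  for (f in c("expansion", "stability", "unfilling")) {
    v <- vapply(vals, `[[`, numeric(1), f)
    expect_lt(max(v) - min(v), 0.05 + 1e-9)
  }
})
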