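test_that("FWHM-to-sigma conversion and smoothing identities hold", {
  expect_equal(glymphalps:::fwhm_to_sigma(8, 2), 1.6986, tolerance = 1e-4)
  grid <- small_grid()
  withr::with_seed(1, {
    v <- scalar_volume(array(stats::runif(prod(grid$shape)), grid$shape), grid)
  })
  expect_identical(smooth_volume(v, 0)$values, v$values)
  expect_error(smooth_volume(v, -1), ">= 0")
  # total intensity conserved for interior-supported input
  blob <- array(0, grid$shape)
  blob[8:12, 10:14, 8:12] <- 3
  sb <- smooth_volume(scalar_volume(blob, grid), 8)
  expect_equal(sum(sb$values), sum(blob), tolerance = 1e-6)
  # constant volume unchanged in the interior
  const <- smooth_volume(scalar_volume(array(2, grid$shape), grid), 6)
  expect_equal(const$values[8:12, 8:12, 8:12],
               array(2, c(5, 5, 5)), tolerance = 1e-9)
})

make_null_glm <- function(n = 30, grid = small_grid(c(12L, 12L, 12L)), seed = 1) {
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * prod(grid$shape)), n)
    attr(Y, "grid") <- grid
    x <- stats::rnorm(n)
    X <- cbind(1, x)
    colnames(X) <- c("(Intercept)", "x")
    list(Y = Y, X = X, mask = array(TRUE, grid$shape))
  })
}

test_that("voxelwise GLM handles degenerate voxels, strong effects and reordering", {
  d <- make_null_glm()
  # constant GM at a voxel -> T = 0, flagged
  d$Y[, 1] <- 5
  sm <- voxelwise_glm(d$Y, d$X, "x", mask = d$mask)
  expect_equal(sm$t[1], 0)
  expect_gte(sm$n_degenerate, 1L)
  expect_equal(sm$df, nrow(d$X) - 2L)
  # GM = 2*x + tiny noise -> T explodes
  withr::with_seed(2, {
    d$Y[, 2] <- 2 * d$X[, 2] + stats::rnorm(nrow(d$X), 0, 1e-8)
  })
  sm2 <- voxelwise_glm(d$Y, d$X, "x", mask = d$mask)
  expect_gt(sm2$t[2], 100)
  # permuting subject order of both design and volumes leaves the map unchanged
  perm <- sample(nrow(d$X))
  Yp <- d$Y[perm, ]; attr(Yp, "grid") <- attr(d$Y, "grid")
  sm3 <- voxelwise_glm(Yp, d$X[perm, ], "x", mask = d$mask)
  expect_equal(sm3$t, sm2$t, tolerance = 1e-8)
  # negating the contrast negates the map
  sm4 <- voxelwise_glm(d$Y, d$X, c(0, -1), mask = d$mask)
  expect_equal(sm4$t, -sm2$t)
  # contract violations
  expect_error(voxelwise_glm(d$Y, cbind(d$X, d$X[, 2]), c(0, 1, 0)), "rank")
  expect_error(voxelwise_glm(d$Y, d$X[-1, ], "x"), "per design row")
})

test_that("max-T corrected p dominates uncorrected p and is deterministic", {
  d <- make_null_glm(n = 25, seed = 5)
  pc <- fwe_threshold_maxT(d$Y, d$X, "x", n_perm = 120, seed = 3, mask = d$mask)
  sm <- attr(pc, "stat_map")
  pu <- stat_map_p(sm)$values
  expect_true(all(pc$values >= pu))
  pc2 <- fwe_threshold_maxT(d$Y, d$X, "x", n_perm = 120, seed = 3, mask = d$mask)
  expect_identical(pc2$values, pc$values)
  expect_error(fwe_threshold_maxT(d$Y, d$X, "x", n_perm = 50), ">= 100")
})

test_that("cluster table keeps only clusters exceeding the extent threshold", {
  grid <- small_grid(c(20L, 20L, 20L))
  tv <- array(0, grid$shape)
  tv[2:7, 2:6, 2:6] <- 8        # 6*5*5 = 150 voxels
  tv[12:15, 12:16, 12:15] <- 8  # 4*5*4 = 80 voxels
  sm <- fake_stat_map(tv, grid)
  ct <- cluster_table(sm, p_voxel = 0.001, min_extent = 100L)
  expect_equal(unique(ct$size), 150L)
  # strict "> min_extent": a 100-voxel blob at threshold 100 is dropped
  tv2 <- array(0, grid$shape)
  tv2[1:4, 1:5, 1:5] <- 8  # exactly 100
  expect_equal(nrow(cluster_table(fake_stat_map(tv2, grid), min_extent = 100L)), 0L)
  ct99 <- cluster_table(fake_stat_map(tv2, grid), min_extent = 99L)
  expect_equal(length(unique(ct99$cluster)), 1L)
  expect_equal(unique(ct99$size), 100L)
  # sub-threshold map -> empty table
  expect_equal(nrow(cluster_table(fake_stat_map(array(0, grid$shape), grid))), 0L)
})

test_that("cluster peaks sit at the constructed maximum with world coordinates", {
  grid <- small_grid(c(21L, 21L, 21L))
  tv <- array(0, grid$shape)
  ctr <- c(11L, 11L, 11L)
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    d2 <- sum((c(i, j, k) - ctr)^2) * 4
    if (d2 <= 64) tv[i, j, k] <- 10 - sqrt(d2) / 2
  }
  sm <- fake_stat_map(tv, grid)
  ct <- cluster_table(sm, min_extent = 10L)
  expect_equal(c(ct$x[1], ct$y[1], ct$z[1]),
               drop(voxel_to_world(grid, ctr - 1L)))
  expect_equal(ct$t[1], 10)
  # peaks are separated by at least peak_sep_mm
  if (nrow(ct) > 1) {
    dmin <- min(dist(as.matrix(ct[c("x", "y", "z")])))
    expect_gte(dmin, 8)
  }
})

test_that("18-connectivity joins edge neighbours but not corner neighbours", {
  m <- array(FALSE, c(4L, 4L, 4L))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE  # edge-adjacent
  m[4, 4, 4] <- TRUE                       # far away
  lab <- glymphalps:::label_components(m, 18L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 1])
  expect_true(lab[4, 4, 4] != lab[1, 1, 1])
  m2 <- array(FALSE, c(3L, 3L, 3L))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE  # corner-adjacent
  lab26 <- glymphalps:::label_components(m2, 26L)
  lab18 <- glymphalps:::label_components(m2, 18L)
  expect_equal(lab26[1, 1, 1], lab26[2, 2, 2])
  expect_true(lab18[1, 1, 1] != lab18[2, 2, 2])
})

test_that("overlap mask intersects cluster maps exactly", {
  grid <- small_grid(c(10L, 10L, 10L))
  a <- array(0, grid$shape); a[1:6, 1:6, 1:6] <- 1
  b <- array(0, grid$shape); b[4:9, 1:6, 1:6] <- 1
  va <- scalar_volume(a, grid); vb <- scalar_volume(b, grid)
  ov <- overlap_mask(va, vb)
  expect_equal(ov$n_voxels, 3L * 6L * 6L)
  expect_equal(ov$mask$values, a * b)
  expect_equal(overlap_mask(va, va)$mask$values, a)  # idempotence
  d <- array(0, grid$shape); d[8:10, 8:10, 8:10] <- 1
  expect_equal(overlap_mask(va, scalar_volume(d, grid))$n_voxels, 0L)
  other <- scalar_volume(array(0, c(9, 10, 10)), small_grid(c(9L, 10L, 10L)))
  expect_error(overlap_mask(va, other), "mismatched grids")
})
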