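test_that("tensor fit inverts the noiseless forward model", {
  gtab <- make_gradient_table(64, 1000)
  withr::with_seed(42, {
    for (r in 1:5) {
      d6 <- random_spd_tensor()
      tv <- uniform_tensor_volume(d6)
      dwi <- simulate_dwi(tv, gtab, s0 = 800, noise_model = "none")
      for (method in c("wls", "ols")) {
        fit <- fit_tensor(dwi, method = method)
        expect_lt(max(abs(fit$values - tv$values)), 1e-9)
      }
    }
  })
  # isotropic signal gives equal diagonal elements
  iso <- uniform_tensor_volume(c(0.7e-3, 0.7e-3, 0.7e-3, 0, 0, 0))
  fit <- fit_tensor(simulate_dwi(iso, gtab, noise_model = "none"))
  expect_equal(tensor_component(fit, "xx"), tensor_component(fit, "yy"))
  expect_equal(tensor_component(fit, "xx"), tensor_component(fit, "zz"))
})

test_that("tensor fit rejects deficient gradient designs", {
  expect_error(make_gradient_table(5, 1000), ">= 6")
  tv <- uniform_tensor_volume(c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  dwi <- simulate_dwi(tv, make_gradient_table(6, 1000), noise_model = "none")
  # collinear directions: rank-deficient design
  gt <- dwi$gtab
  gt$gx[-1] <- 1; gt$gy[-1] <- 0; gt$gz[-1] <- 0
  expect_error(fit_tensor(dwi, gtab = gt), "non-collinear")
  # no b = 0 frame
  gt2 <- dwi$gtab; gt2$b[1] <- 1000; gt2$gx[1] <- 1
  expect_error(fit_tensor(dwi, gtab = gt2), "b = 0")
  # frame-count mismatch
  expect_error(fit_tensor(dwi, gtab = dwi$gtab[1:5, ]), "frames")
})

test_that("fractional anisotropy matches hand-computed values", {
  expect_equal(fractional_anisotropy(
    uniform_tensor_volume(c(1e-3, 1e-3, 1e-3, 0, 0, 0)))$values[1, 1, 1], 0)
  expect_equal(fractional_anisotropy(
    uniform_tensor_volume(c(1, 0, 0, 0, 0, 0)))$values[1, 1, 1], 1)
  fa <- fractional_anisotropy(
    uniform_tensor_volume(c(1.2e-3, 0.4e-3, 0.4e-3, 0, 0, 0)))
  expect_equal(fa$values[1, 1, 1], 0.6030, tolerance = 1e-3)
  # degenerate all-zero tensor -> 0 by convention
  expect_equal(fractional_anisotropy(
    uniform_tensor_volume(c(0, 0, 0, 0, 0, 0)))$values[1, 1, 1], 0)
  # rotation invariance: FA from off-diagonal representation of same spectrum
  R <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3)))
  D <- R %*% diag(c(1.2e-3, 0.4e-3, 0.4e-3)) %*% t(R)
  fa_rot <- fractional_anisotropy(uniform_tensor_volume(
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])))
  expect_equal(fa_rot$values[1, 1, 1], 0.6030227, tolerance = 1e-6)
})

test_that("ROI means average the named diagonal elements", {
  grid <- volume_grid(c(16L, 16L, 8L), c(2, 2, 2))
  masks <- make_roi_masks(grid)
  vals <- array(0, dim = c(grid$shape, 6L))
  vals[, , , 1] <- 1.3e-3; vals[, , , 2] <- 0.8e-3; vals[, , , 3] <- 0.9e-3
  tv <- glymphalps:::tensor_volume(vals, grid)
  m <- roi_mean_diffusivities(tv, masks)
  expect_equal(m$dxx_proj, c(1.3e-3, 1.3e-3))
  expect_equal(m$dyy_assoc, c(0.8e-3, 0.8e-3))
  # identity transform is a no-op
  m2 <- roi_mean_diffusivities(tv, masks, transform = diag(4))
  expect_equal(m2, m)
  # two-voxel mask mean is the hand mean
  dxx <- tensor_component(tv, "xx")
  idx <- which(masks$proj_left)[1:2]
  dxx[idx] <- c(1.0e-3, 2.0e-3)
  vals[, , , 1] <- dxx
  tv2 <- glymphalps:::tensor_volume(vals, grid)
  m3 <- roi_mean_diffusivities(tv2, masks)
  n <- sum(masks$proj_left)
  expect_equal(m3$dxx_proj[1], (1.0e-3 + 2.0e-3 + (n - 2) * 1.3e-3) / n)
})

test_that("a translated subject grid recovers template ROI means via the transform", {
  grid <- volume_grid(c(16L, 16L, 8L), c(2, 2, 2))
  masks <- make_roi_masks(grid)
  # subject grid shifted 6 mm in world space
  aff <- grid$affine; aff[1:3, 4] <- aff[1:3, 4] + c(6, 0, 0)
  sub_grid <- volume_grid(grid$shape, affine = aff)
  vals <- array(0, dim = c(grid$shape, 6L))
  vals[, , , 1:3] <- 1e-3
  tv <- glymphalps:::tensor_volume(vals, sub_grid)
  # transform maps subject world coords back to template world coords
  tr <- diag(4); tr[1, 4] <- -6
  m <- suppressWarnings(roi_mean_diffusivities(tv, masks, transform = tr))
  expect_equal(m$dxx_proj, c(1e-3, 1e-3))
})

test_that("ALPS index follows its defining ratio and bilateral average", {
  mk <- function(dxx_p, dyy_p, dxx_a, dzz_a, side = "left") {
    tibble::tibble(side = side, dxx_proj = dxx_p, dyy_proj = dyy_p,
                   dzz_proj = 9e-4, dxx_assoc = dxx_a, dyy_assoc = 9e-4,
                   dzz_assoc = dzz_a)
  }
  # hand arithmetic: mean(1.4, 1.0)/mean(0.6, 0.6) = 2.0
  means <- dplyr::bind_rows(mk(1.4e-3, 0.6e-3, 1.0e-3, 0.6e-3, "left"),
                            mk(1.4e-3, 0.6e-3, 1.0e-3, 0.6e-3, "right"))
  idx <- alps_index(means)
  expect_equal(idx$alps_left, 2.0)
  # equal used means -> 1.0
  eq <- dplyr::bind_rows(mk(7e-4, 7e-4, 7e-4, 7e-4, "left"),
                         mk(7e-4, 7e-4, 7e-4, 7e-4, "right"))
  expect_equal(alps_index(eq)$alps_bilateral, 1.0)
  # bilateral is the mean of sides: 1.2 and 1.4 -> 1.3
  lr <- dplyr::bind_rows(mk(1.2e-3, 1e-3, 1.2e-3, 1e-3, "left"),
                         mk(1.4e-3, 1e-3, 1.4e-3, 1e-3, "right"))
  got <- alps_index(lr)
  expect_equal(got$alps_left, 1.2)
  expect_equal(got$alps_right, 1.4)
  expect_equal(got$alps_bilateral, 1.3)
  # zero denominator names the side
  bad <- dplyr::bind_rows(mk(1e-3, 0, 1e-3, 0, "left"),
                          mk(1e-3, 1e-3, 1e-3, 1e-3, "right"))
  expect_error(alps_index(bad), "left")
})

test_that("ALPS is scale-invariant, ignores unused diffusivities, and is monotone", {
  withr::with_seed(7, {
    for (r in 1:20) {
      d <- stats::runif(6, 0.3e-3, 2e-3)
      means <- tibble::tibble(
        side = c("left", "right"),
        dxx_proj = d[1], dyy_proj = d[2], dzz_proj = d[3],
        dxx_assoc = d[4], dyy_assoc = d[5], dzz_assoc = d[6]
      )
      base <- alps_index(means)$alps_bilateral
      # scale invariance
      sc <- dplyr::mutate(means, dplyr::across(-side, ~ .x * 3.7))
      expect_equal(alps_index(sc)$alps_bilateral, base, tolerance = 1e-12)
      # Dzzproj, Dyyassoc recorded but unused
      alt <- dplyr::mutate(means, dzz_proj = 9, dyy_assoc = -4)
      expect_equal(alps_index(alt)$alps_bilateral, base)
      # monotone: up in numerator terms, down in denominator terms
      expect_gt(alps_index(dplyr::mutate(means, dxx_proj = dxx_proj * 1.1))$alps_bilateral, base)
      expect_gt(alps_index(dplyr::mutate(means, dxx_assoc = dxx_assoc * 1.1))$alps_bilateral, base)
      expect_lt(alps_index(dplyr::mutate(means, dyy_proj = dyy_proj * 1.1))$alps_bilateral, base)
      expect_lt(alps_index(dplyr::mutate(means, dzz_assoc = dzz_assoc * 1.1))$alps_bilateral, base)
    }
  })
})
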