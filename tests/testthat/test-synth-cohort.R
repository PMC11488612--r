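test_that("fiber ROI slabs are 5 mm thick, disjoint, nonempty and mirror-symmetric", {
  grid <- volume_grid(c(40L, 48L, 40L), c(2, 2, 2))
  masks <- make_roi_masks(grid)
  nm <- c("proj_left", "proj_right", "assoc_left", "assoc_right")
  # 5 mm at 2 mm voxels -> ceil(5/2) = 3 voxels thick in z
  for (m in nm) {
    zext <- range(which(apply(masks[[m]], 3, any)))
    expect_equal(diff(zext) + 1L, 3L)
    expect_gt(sum(masks[[m]]), 0)
  }
  total <- masks$proj_left + masks$proj_right + masks$assoc_left + masks$assoc_right
  expect_lte(max(total), 1)  # pairwise disjoint
  # mirror across the mid-sagittal plane
  expect_identical(masks$proj_left[grid$shape[1]:1, , ], masks$proj_right)
  expect_identical(masks$assoc_left[grid$shape[1]:1, , ], masks$assoc_right)
  expect_error(make_roi_masks(volume_grid(c(4L, 4L, 2L), c(2, 2, 2))),
               "too small")
})

test_that("analytic ALPS of a noiseless tensor field equals the latent value", {
  masks <- make_roi_masks(volume_grid(c(40L, 48L, 40L), c(2, 2, 2)))
  for (x in seq(0.8, 2.0, by = 0.2)) {
    tf <- simulate_tensor_field(x, masks)
    idx <- alps_index(roi_mean_diffusivities(tf, masks))
    expect_equal(idx$alps_bilateral, x, tolerance = 1e-6)
  }
  # x = 1 gives isotropic ROI tensors
  tf1 <- simulate_tensor_field(1, masks)
  expect_equal(tensor_component(tf1, "xx")[masks$proj_left],
               tensor_component(tf1, "zz")[masks$proj_left])
  expect_error(simulate_tensor_field(50, masks), "physiological")
  expect_error(simulate_tensor_field(-1, masks), "> 0")
})

test_that("DWI forward model matches the closed form and is seed-deterministic", {
  gtab <- make_gradient_table(64, 1000)
  expect_true(all(abs(sqrt(gtab$gx^2 + gtab$gy^2 + gtab$gz^2)[gtab$b > 0] - 1) < 1e-8))
  expect_gte(sum(gtab$b == 0), 1L)
  tv <- uniform_tensor_volume(c(0.7e-3, 0.7e-3, 0.7e-3, 0, 0, 0))
  dwi <- simulate_dwi(tv, gtab, s0 = 1000, noise_model = "none")
  # isotropic D: S/s0 = exp(-b*D) for any unit direction
  expect_equal(unique(round(dwi$values[1, 1, 1, gtab$b > 0] / 1000, 10)),
               round(exp(-0.7), 10))
  expect_equal(dwi$values[1, 1, 1, which(gtab$b == 0)[1]], 1000)
  d1 <- simulate_dwi(tv, gtab, noise_sd = 50, noise_model = "rician", seed = 9L)
  d2 <- simulate_dwi(tv, gtab, noise_sd = 50, noise_model = "rician", seed = 9L)
  expect_identical(d1$values, d2$values)
  expect_error(simulate_dwi(tv, gtab, noise_sd = -1, noise_model = "gaussian"),
               ">= 0")
})

test_that("simulated cohorts have the configured group structure", {
  p <- synth_params(n_yoad = 130L, n_ctl = 137L, seed = 11L)
  sim <- suppressMessages(simulate_subjects(p, keep_volumes = FALSE))
  expect_equal(sum(sim$cohort$group == "YOAD"), 130L)
  x <- sim$truth$x
  expect_lt(mean(x[sim$truth$group == "YOAD"]),
            mean(x[sim$truth$group == "CTL"]))
  # determinism
  sim2 <- suppressMessages(simulate_subjects(p, keep_volumes = FALSE))
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$volume_fn(5, "gm")$values, sim2$volume_fn(5, "gm")$values)
  # volumes physically sane
  gm <- sim$volume_fn(1, "gm")
  expect_true(all(gm$values >= 0))
  tv <- sim$volume_fn(1, "tensor")
  expect_true(all(tv$values[, , , 1:3] > 0))
  # scores within their printed ranges
  info <- cognitive_score_info()
  for (k in seq_len(nrow(info))) {
    v <- sim$cohort[[info$test[k]]]
    expect_true(all(v >= 0 & v <= info$max[k]))
  }
})

test_that("a = 0 decouples the mediator from latent ALPS", {
  p <- synth_params(n_yoad = 250L, n_ctl = 250L,
                    mediation = list(a = 0, b = 0.35, c_prime = 0,
                                     sd_m = 12, sd_y = 8, m0 = 700),
                    seed = 21L)
  sim <- suppressMessages(simulate_subjects(p, keep_volumes = FALSE))
  expect_lt(abs(stats::cor(sim$truth$x, sim$truth$m)), 0.1)
})

test_that("mediation truth is recovered from the generated cohort", {
  # structural a, b, c' recovered within 3 SE in >= 95% of replications
  ok <- logical(100)
  for (r in 1:100) {
    p <- synth_params(seed = 3000L + r)
    sim <- suppressMessages(simulate_subjects(p, keep_volumes = FALSE))
    tr <- sim$truth
    fp <- fit_paths(tr$x, tr$m, tr$y_raw)
    truth <- c(a = p$mediation$a, b = p$mediation$b,
               c_prime = p$mediation$c_prime)
    ok[r] <- all(abs(fp$estimate[match(names(truth), fp$path)] - truth) <=
                   3 * fp$std_error[match(names(truth), fp$path)])
  }
  expect_gte(mean(ok), 0.95)
})
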