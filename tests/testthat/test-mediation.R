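test_that("sphere masks match the brute-force enumeration oracle", {
  g2 <- volume_grid(c(21L, 21L, 21L), c(2, 2, 2))
  g1 <- volume_grid(c(21L, 21L, 21L), c(1, 1, 1))
  expect_equal(sum(sphere_mask(c(0, 0, 0), 4, g2)$mask),
               brute_force_sphere_count(4, 2))  # 33
  expect_equal(sum(sphere_mask(c(0, 0, 0), 4, g1)$mask),
               brute_force_sphere_count(4, 1))  # 257
  expect_equal(brute_force_sphere_count(4, 2), 33L)
  expect_equal(brute_force_sphere_count(4, 1), 257L)
  # radius 0 keeps exactly the center voxel
  s0 <- sphere_mask(c(0, 0, 0), 0, g2)
  expect_equal(sum(s0$mask), 1L)
  expect_true(s0$mask[11, 11, 11])
  expect_error(sphere_mask(c(500, 0, 0), 4, g2), "outside")
  # inclusive boundary: voxel centers at exactly radius distance included
  s <- sphere_mask(c(0, 0, 0), 2, g2)
  expect_equal(sum(s$mask), 7L)  # center + 6 face neighbours at exactly 2 mm
})

test_that("seed volume extraction is sum * voxel volume and linear in GM", {
  g2 <- volume_grid(c(21L, 21L, 21L), c(2, 2, 2))
  seed <- sphere_mask(c(0, 0, 0), 4, g2)
  ones <- scalar_volume(array(1, g2$shape), g2)
  expect_equal(extract_seed_volume(ones, seed), 33 * 8)
  zeros <- scalar_volume(array(0, g2$shape), g2)
  expect_equal(extract_seed_volume(zeros, seed), 0)
  withr::with_seed(3, {
    gm <- scalar_volume(array(stats::runif(prod(g2$shape)), g2$shape), g2)
  })
  v1 <- extract_seed_volume(gm, seed)
  gm2 <- scalar_volume(gm$values * 2, g2)
  expect_equal(extract_seed_volume(gm2, seed), 2 * v1)
})

test_that("path fits reproduce the worked 4-point example and the c identity", {
  p <- suppressWarnings(fit_paths(c(0, 1, 2, 3), c(1, 1, 3, 3), c(1, 1, 3, 3)))
  est <- stats::setNames(p$estimate, p$path)
  expect_equal(unname(est["a"]), 0.8, tolerance = 1e-10)
  expect_equal(unname(est["b"]), 1, tolerance = 1e-10)
  expect_equal(unname(est["c_prime"]), 0, tolerance = 1e-10)
  expect_equal(unname(est["c"]), 0.8, tolerance = 1e-10)
  expect_equal(unname(est["a"] * est["b"]), 0.8, tolerance = 1e-10)
  # c = c' + a*b exactly for OLS on random data
  withr::with_seed(11, {
    for (r in 1:10) {
      n <- 40
      x <- stats::rnorm(n); m <- 0.3 * x + stats::rnorm(n)
      y <- 0.5 * m - 0.2 * x + stats::rnorm(n)
      f <- fit_paths(x, m, y)
      e <- stats::setNames(f$estimate, f$path)
      expect_equal(unname(e["c"]), unname(e["c_prime"] + e["a"] * e["b"]),
                   tolerance = 1e-10)
    }
  })
  expect_error(fit_paths(rep(1, 20), stats::rnorm(20), stats::rnorm(20)),
               "constant")
  expect_error(fit_paths(1:20, 2 * (1:20) + 3, stats::rnorm(20)),
               "exact linear")
})

test_that("null paths are estimated near zero", {
  withr::with_seed(8, {
    n <- 1000
    x <- stats::rnorm(n)
    m <- stats::rnorm(n)             # a = 0 truth
    y <- 0.4 * m + stats::rnorm(n)
    f <- fit_paths(x, m, y)
    a_row <- f[f$path == "a", ]
    expect_lt(abs(a_row$estimate), 3 * a_row$std_error)
    # with a = 0, total and direct effects coincide up to noise
    e <- stats::setNames(f$estimate, f$path)
    expect_equal(unname(e["c"]), unname(e["c_prime"]), tolerance = 0.05)
  })
})

test_that("bias correction reduces to the percentile interval when z0 = 0", {
  withr::with_seed(21, {
    n <- 120
    x <- stats::rnorm(n); m <- 0.5 * x + stats::rnorm(n)
    y <- 0.5 * m + stats::rnorm(n)
  })
  bt <- bootstrap_indirect(x, m, y, B = 400, seed = 5)
  # recompute percentile interval at the shifted probabilities
  probs <- stats::pnorm(2 * bt$z0 + stats::qnorm(c(0.025, 0.975)))
  expect_equal(unname(stats::quantile(bt$boot, probs, type = 6)),
               c(bt$ci_lower, bt$ci_upper))
  # symmetric case: z0 = 0 forces plain percentile endpoints
  boot_sym <- bt$boot - stats::median(bt$boot) + bt$indirect
  prop <- sum(boot_sym < bt$indirect) / length(boot_sym)
  z0_sym <- stats::qnorm(prop)
  expect_lt(abs(z0_sym), 0.05)
  # determinism under a fixed seed
  bt2 <- bootstrap_indirect(x, m, y, B = 400, seed = 5)
  expect_identical(bt$boot, bt2$boot)
  expect_identical(c(bt$ci_lower, bt$ci_upper), c(bt2$ci_lower, bt2$ci_upper))
  expect_error(bootstrap_indirect(x, m, y, B = 50), ">= 100")
})

test_that("mediation classification follows the CI and direct-path rules", {
  expect_equal(classify_mediation(0.05, 0.30, 0.40), "full")
  expect_equal(classify_mediation(0.05, 0.30, 0.01), "partial")
  expect_equal(classify_mediation(-0.05, 0.30, 0.01), "none")
  expect_equal(classify_mediation(-0.30, -0.05, 0.50), "full")
})

test_that("mediate() runs the full chain on a cohort table", {
  withr::with_seed(31, {
    n <- 150
    d <- tibble::tibble(
      alps = stats::rnorm(n, 1.4, 0.1),
      gmvol = 200 + 300 * (alps - 1.4) + stats::rnorm(n, 0, 10),
      casi = 90 + 0.4 * (gmvol - 200) + stats::rnorm(n, 0, 5),
      age = stats::rnorm(n, 60, 5)
    )
  })
  fit <- mediate(d, "alps", "gmvol", "casi", B = 500, seed = 2)
  expect_s3_class(fit, "mediation_fit")
  expect_equal(fit$classification, "full")
  td <- tidy(fit)
  expect_setequal(td$term, c("a", "b", "c_prime", "c", "indirect"))
  gl <- glance(fit)
  expect_equal(gl$B, 500L)
  expect_equal(gl$n, n)
  # covariates are appended to every fit without breaking the chain
  fit_cov <- mediate(d, "alps", "gmvol", "casi", covariates = "age",
                     B = 500, seed = 2)
  expect_equal(fit_cov$classification, "full")
  expect_error(mediate(d, "alps", "missing", "casi"), "not in data")
})
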