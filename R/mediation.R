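#' Spherical seed mask
#'
#' Builds the binary mask of all voxels whose centers lie within
#' `radius_mm` (inclusive) of a world-coordinate center — the seed geometry
#' used to extract mediator GM volumes at cluster peaks (default radius
#' 4 mm). An optional affine transports the template-space sphere to a
#' subject grid by nearest-neighbour resampling.
#'
#' @param center_mm World coordinates of the sphere center, mm.
#' @param radius_mm Sphere radius, mm (>= 0; radius 0 keeps exactly the
#'   voxel containing the center).
#' @param grid Template [volume_grid()].
#' @param subject_grid Optional target grid to transport the mask onto.
#' @param transform Optional 4x4 affine mapping subject world mm to template
#'   world mm (identity when omitted).
#' @return A `sphere_seed`: list with `mask` (logical array), `center_mm`,
#'   `radius_mm`, `grid`.
#' @export
sphere_mask <- function(center_mm, radius_mm = 4, grid,
                        subject_grid = NULL, transform = NULL) {
  if (radius_mm < 0) stop("radius must be >= 0", call. = FALSE)
  center_mm <- as.numeric(center_mm)
  ijk <- as.matrix(expand.grid(i = seq_len(grid$shape[1]) - 1L,
                               j = seq_len(grid$shape[2]) - 1L,
                               k = seq_len(grid$shape[3]) - 1L))
  xyz <- voxel_to_world(grid, ijk)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2
  if (radius_mm == 0) {
    # the voxel whose center is nearest to the requested point
    inside <- seq_along(d2) == which.min(d2)
    vox <- round(world_to_voxel(grid, matrix(center_mm, 1)))
    if (any(vox < 0) || any(vox >= grid$shape - 0L)) {
      stop("sphere center outside grid", call. = FALSE)
    }
  }
  mask <- array(inside, dim = grid$shape)
  out_grid <- grid
  if (!is.null(subject_grid)) {
    mask <- resample_mask_nn(mask, grid, subject_grid, transform)
    out_grid <- subject_grid
  }
  if (!any(mask)) stop("empty sphere mask: center outside grid?", call. = FALSE)
  structure(list(mask = mask, center_mm = center_mm, radius_mm = radius_mm,
                 grid = out_grid),
            class = "sphere_seed")
}

#' Extract a seed GM volume
#'
#' Sums the modulated GM values over the seed voxels and multiplies by the
#' voxel volume, giving a volume-like quantity in mm^3-equivalent modulated
#' units — the per-subject mediator.
#'
#' @param gm A [scalar_volume()] on the seed's grid.
#' @param seed A `sphere_seed` from [sphere_mask()].
#' @return A single number.
#' @export
extract_seed_volume <- function(gm, seed) {
  stopifnot(inherits(gm, "scalar_volume"), inherits(seed, "sphere_seed"))
  if (!grids_equal(gm$grid, seed$grid)) {
    stop("GM volume and seed mask on mismatched grids", call. = FALSE)
  }
  if (!any(seed$mask)) stop("empty seed mask", call. = FALSE)
  sum(gm$values[seed$mask]) * voxel_volume(gm$grid)
}

ols_paths <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xa <- cbind(1, x, C)
  Xb <- cbind(1, x, m, C)
  fa <- .lm.fit(Xa, m)
  fb <- .lm.fit(Xb, y)
  fc <- .lm.fit(Xa, y)
  c(a = fa$coefficients[2], b = fb$coefficients[3],
    c_prime = fb$coefficients[2], c = fc$coefficients[2])
}

path_fit_row <- function(X, yv, col, path) {
  n <- nrow(X); p <- ncol(X)
  fit <- .lm.fit(X, yv)
  rss <- sum(fit$residuals^2)
  df <- n - p
  s2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[col, col])
  est <- fit$coefficients[col]
  stat <- est / se
  tibble::tibble(path = path, estimate = est, std_error = se,
                 statistic = stat,
                 p_value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE),
                 df = df)
}

#' Simple-mediation path coefficients
#'
#' Preacher-Hayes simple mediation by three OLS fits: `M ~ X` (path a),
#' `Y ~ X + M` (paths c' and b), and `Y ~ X` (total effect c), each with the
#' optional covariates appended. Coefficients are unstandardized, with
#' standard errors and two-sided Student-t p-values. For OLS on a common
#' sample the identity `c = c' + a*b` holds exactly.
#'
#' @param x Predictor (e.g. ALPS index), numeric vector.
#' @param m Mediator (e.g. seed GM volume).
#' @param y Outcome (e.g. cognitive score).
#' @param covariates Optional numeric matrix/data frame of covariates
#'   appended to every fit.
#' @return A `mediation_paths` tibble with rows `a`, `b`, `c_prime`, `c` and
#'   columns `estimate`, `std_error`, `statistic`, `p_value`, `df`; the
#'   sample size is in attribute `n`.
#' @export
fit_paths <- function(x, m, y, covariates = NULL) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y lengths differ", call. = FALSE)
  if (n < 4L) stop("need at least 4 complete cases", call. = FALSE)
  if (n < 10L) warning("fewer than 10 complete cases; estimates unstable", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(m) == 0) {
    stop("constant predictor or mediator", call. = FALSE)
  }
  if (abs(stats::cor(x, m)) > 1 - 1e-12) {
    stop("mediator is an exact linear function of the predictor", call. = FALSE)
  }
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xa <- cbind(1, x, C)
  Xb <- cbind(1, x, m, C)
  out <- dplyr::bind_rows(
    path_fit_row(Xa, m, 2L, "a"),
    path_fit_row(Xb, y, 3L, "b"),
    path_fit_row(Xb, y, 2L, "c_prime"),
    path_fit_row(Xa, y, 2L, "c")
  )
  if (any(out$std_error == 0)) {
    warning("zero residual variance: standard errors degenerate", call. = FALSE)
  }
  attr(out, "n") <- n
  class(out) <- c("mediation_paths", class(out))
  out
}

#' Bias-corrected bootstrap CI for the indirect effect
#'
#' Case-resampling bootstrap of the rows of (x, m, y, covariates). Each
#' resample yields `a* x b*`; the bias-correction factor is
#' `z0 = qnorm(#{a*b* < a_hat*b_hat} / B)` (strict less-than; `z0 = 0` when
#' all bootstrap values equal the estimate), and the CI endpoints are the
#' empirical quantiles of the bootstrap distribution at
#' `pnorm(2*z0 +/- qnorm(1 - alpha/2))`. Degenerate resamples (constant
#' predictor or mediator) are redrawn and counted; more than 10% redraws is
#' an error.
#'
#' @inheritParams fit_paths
#' @param B Number of bootstrap resamples (>= 100; default practice for
#'   bias-corrected mediation intervals is 1000).
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @param seed Integer seed for the resampling stream.
#' @return A list: `indirect` (point estimate `a_hat*b_hat`), `ci_lower`,
#'   `ci_upper`, `z0`, `B`, `alpha`, `seed`, `n_redrawn`, and the bootstrap
#'   draws `boot`.
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, B = 1000L,
                               alpha = 0.05, seed = 1L) {
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  n <- length(x)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  est <- ols_paths(x, m, y, C)
  indirect <- unname(est["a"] * est["b"])
  boot <- numeric(B)
  n_redrawn <- 0L
  max_redraw <- ceiling(0.1 * B)
  withr::with_seed(as.integer(seed), {
    for (bb in seq_len(B)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        xs <- x[idx]; ms <- m[idx]
        if (stats::var(xs) > 0 && stats::var(ms) > 0 &&
            abs(stats::cor(xs, ms)) < 1 - 1e-12) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraw) {
          stop("more than 10% of bootstrap resamples degenerate", call. = FALSE)
        }
      }
      eb <- ols_paths(xs, ms, y[idx], if (is.null(C)) NULL else C[idx, , drop = FALSE])
      boot[bb] <- eb["a"] * eb["b"]
    }
  })
  prop <- sum(boot < indirect) / B
  z0 <- if (all(boot == indirect)) 0 else {
    stats::qnorm(min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B)))
  }
  zc <- stats::qnorm(1 - alpha / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(boot, probs, type = 6))
  if (ci[1] > indirect || ci[2] < indirect) {
    message("BC interval does not bracket the point estimate (allowed by the BC definition)")
  }
  list(indirect = indirect, ci_lower = ci[1], ci_upper = ci[2], z0 = z0,
       B = as.integer(B), alpha = alpha, seed = as.integer(seed),
       n_redrawn = n_redrawn, boot = boot)
}

#' Classify a mediation result
#'
#' `none` when the bootstrap CI for the indirect effect contains zero;
#' otherwise `full` when the direct path c' is non-significant at `alpha`,
#' else `partial`.
#'
#' @param ci_lower,ci_upper Bootstrap CI endpoints for the indirect effect.
#' @param c_prime_p Two-sided p-value of the direct path c'.
#' @param alpha Significance level (default 0.05).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_mediation <- function(ci_lower, ci_upper, c_prime_p, alpha = 0.05) {
  if (ci_lower <= 0 && ci_upper >= 0) return("none")
  if (is.na(c_prime_p) || c_prime_p >= alpha) "full" else "partial"
}

#' Mediation analysis on a cohort table
#'
#' Data-frame-first wrapper running the full Preacher-Hayes analysis:
#' listwise deletion on the used columns, path fits ([fit_paths()]),
#' bias-corrected bootstrap CI for the indirect effect
#' ([bootstrap_indirect()]), and classification ([classify_mediation()]).
#'
#' @param data A data frame (e.g. the cohort table joined with extracted
#'   seed volumes).
#' @param x,m,y Column names of predictor, mediator and outcome.
#' @param covariates Optional character vector of covariate columns.
#' @param B,alpha,seed Passed to [bootstrap_indirect()].
#' @return A `mediation_fit` object; see [tidy.mediation_fit()] and
#'   [glance.mediation_fit()].
#' @export
mediate <- function(data, x, m, y, covariates = NULL, B = 1000L,
                    alpha = 0.05, seed = 1L) {
  cols <- c(x, m, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[cols]
  cc <- stats::complete.cases(d)
  if (sum(!cc) > 0) message(sum(!cc), " row(s) dropped (listwise deletion)")
  d <- d[cc, ]
  cov_m <- if (is.null(covariates)) NULL else as.matrix(d[covariates])
  paths <- fit_paths(d[[x]], d[[m]], d[[y]], cov_m)
  bt <- bootstrap_indirect(d[[x]], d[[m]], d[[y]], cov_m, B = B,
                           alpha = alpha, seed = seed)
  cls <- classify_mediation(bt$ci_lower, bt$ci_upper,
                            paths$p_value[paths$path == "c_prime"], alpha)
  structure(
    list(paths = paths, indirect = bt$indirect, ci_lower = bt$ci_lower,
         ci_upper = bt$ci_upper, z0 = bt$z0, B = bt$B, alpha = alpha,
         seed = bt$seed, boot = bt$boot, n_redrawn = bt$n_redrawn,
         classification = cls, n = attr(paths, "n"),
         variables = list(x = x, m = m, y = y, covariates = covariates)),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> ", x$variables$x, " -> ", x$variables$m, " -> ",
      x$variables$y, " (n = ", x$n, ")\n", sep = "")
  print(as.data.frame(x$paths), row.names = FALSE, digits = 4)
  cat(sprintf("indirect a*b = %.4g, %d%% BC bootstrap CI [%.4g, %.4g] (B = %d)\n",
              x$indirect, round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper, x$B))
  cat("classification:", x$classification, "\n")
  invisible(x)
}
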