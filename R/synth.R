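#' Parameters of the synthetic two-group cohort
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate the
#' study design the pipeline is meant to exercise: 130 young-onset Alzheimer
#' patients (YOAD) vs 137 age-matched controls (CTL) on a shared 2-mm
#' template grid, a negative group shift in the latent ALPS index, regional
#' gray-matter (GM) volume coupled to ALPS, and cognitive outcomes generated
#' from a structural mediation model X -> M -> Y.
#'
#' @param n_yoad,n_ctl Group sizes.
#' @param grid Shared template [volume_grid()] (default 40 x 48 x 40 at 2 mm).
#' @param alps_mean_ctl Control-group mean of the latent ALPS index
#'   (dimensionless; healthy adults typically sit around 1.4-1.5).
#' @param alps_shift_yoad Additive shift of the YOAD group mean (negative:
#'   patients lower).
#' @param alps_sd Between-subject SD of latent ALPS within group.
#' @param d_perp Perpendicular ("penalized") diffusivity in the fiber ROIs,
#'   mm^2/s; the latent ALPS value scales Dxx against this.
#' @param d_background Isotropic background diffusivity, mm^2/s.
#' @param diffusivity_range Physiological clamp on generated diffusivities,
#'   mm^2/s.
#' @param gm_coupling Slope of the directly-coupled GM region's intensity on
#'   latent ALPS (GM intensity units per ALPS unit).
#' @param mediation List with unstandardized structural paths `a` (mediator
#'   units per ALPS unit), `b` (outcome units per mediator unit), `c_prime`
#'   (direct effect), noise SDs `sd_m`, `sd_y`, and mediator baseline `m0`
#'   (mm^3-equivalent seed-region volume at the control ALPS mean).
#' @param score_loading Correlation loading tying each printed cognitive
#'   score to the latent outcome Y (scores get independent residual noise).
#' @param dwi List: `b_value` (s/mm^2), `n_directions`, `n_b0`, `s0`,
#'   `noise_sd` (signal units), `noise_model` one of "rician", "gaussian",
#'   "none".
#' @param gm List: `background` GM intensity inside the brain ellipsoid,
#'   `noise_sd` voxelwise white-noise SD, `region_radius_mm` radius of the
#'   designated coherent regions, `seed_center_mm` (left-hemisphere mediation
#'   seed region center, world mm), `coupled_center_mm` (right-hemisphere
#'   directly-coupled region), `brain_fraction` ellipsoid semi-axes as a
#'   fraction of the half field of view.
#' @param covariates Per-group age/education (mean, sd), shared eTIV
#'   (mean, sd, ml) and female proportions.
#' @param seed Integer run seed; every random draw derives from it.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(n_yoad = 130L,
                         n_ctl = 137L,
                         grid = volume_grid(c(40L, 48L, 40L), c(2, 2, 2)),
                         alps_mean_ctl = 1.45,
                         alps_shift_yoad = -0.15,
                         alps_sd = 0.10,
                         d_perp = 0.6e-3,
                         d_background = 0.7e-3,
                         diffusivity_range = c(1e-4, 3.5e-3),
                         gm_coupling = 0.3,
                         mediation = list(a = 250, b = 0.35, c_prime = 0,
                                          sd_m = 12, sd_y = 8, m0 = 700),
                         score_loading = 0.85,
                         dwi = list(b_value = 1000, n_directions = 64L,
                                    n_b0 = 1L, s0 = 1000, noise_sd = 30,
                                    noise_model = "rician"),
                         gm = list(background = 0.5, noise_sd = 0.05,
                                   region_radius_mm = 7,
                                   seed_center_mm = c(-24, -20, 8),
                                   coupled_center_mm = c(24, -20, 8),
                                   brain_fraction = 0.85),
                         covariates = list(
                           age = list(ctl = c(58.52, 5.71), yoad = c(60.15, 3.67)),
                           education = list(ctl = c(12.47, 3.63), yoad = c(9.59, 4.38)),
                           etiv = c(1450, 130),
                           female_prop = list(ctl = 77 / 137, yoad = 78 / 130)),
                         seed = 1L) {
  p <- list(n_yoad = as.integer(n_yoad), n_ctl = as.integer(n_ctl),
            grid = grid, alps_mean_ctl = alps_mean_ctl,
            alps_shift_yoad = alps_shift_yoad, alps_sd = alps_sd,
            d_perp = d_perp, d_background = d_background,
            diffusivity_range = diffusivity_range, gm_coupling = gm_coupling,
            mediation = mediation, score_loading = score_loading, dwi = dwi,
            gm = gm, covariates = covariates, seed = as.integer(seed))
  sds <- c(alps_sd, mediation$sd_m, mediation$sd_y, dwi$noise_sd, gm$noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (p$dwi$n_directions < 6L) {
    stop("need >= 6 gradient directions for tensor fitting", call. = FALSE)
  }
  if (p$dwi$b_value <= 0) stop("b_value must be > 0", call. = FALSE)
  if (p$n_yoad < 1L || p$n_ctl < 1L) stop("group sizes must be >= 1", call. = FALSE)
  structure(p, class = "synth_params")
}

#' Gradient table for synthetic diffusion-weighted imaging
#'
#' Builds a single-shell gradient table: `n_b0` unweighted frames followed by
#' `n_directions` unit vectors distributed quasi-uniformly on the sphere by a
#' Fibonacci spiral (deterministic, pairwise non-collinear).
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6).
#' @param b_value Shell b-value, s/mm^2.
#' @param n_b0 Number of b = 0 frames (>= 1).
#' @return A tibble with columns `gx`, `gy`, `gz`, `b`.
#' @export
make_gradient_table <- function(n_directions = 64L, b_value = 1000,
                                n_b0 = 1L) {
  if (n_directions < 6L) stop("need >= 6 directions", call. = FALSE)
  if (n_b0 < 1L) stop("need >= 1 b = 0 frame", call. = FALSE)
  if (b_value <= 0) stop("b_value must be > 0", call. = FALSE)
  i <- seq_len(n_directions) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(gx = r * cos(phi), gy = r * sin(phi), gz = z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  tibble::tibble(
    gx = c(rep(0, n_b0), dirs[, 1]),
    gy = c(rep(0, n_b0), dirs[, 2]),
    gz = c(rep(0, n_b0), dirs[, 3]),
    b = c(rep(0, n_b0), rep(b_value, n_directions))
  )
}

#' Fiber ROI masks at the lateral-ventricle-body level
#'
#' Places four disjoint 5-mm-thick slab masks (thickness rounded up to whole
#' voxels) on the template grid: projection-fiber (corona radiata) and
#' association-fiber (superior longitudinal fasciculus) ROIs, one of each per
#' hemisphere, mirror-symmetric about the mid-sagittal plane.
#'
#' @param grid A [volume_grid()].
#' @param thickness_mm Slab thickness along z (default 5 mm).
#' @return A `roi_mask_set`: list of logical arrays `proj_left`,
#'   `proj_right`, `assoc_left`, `assoc_right` plus the grid.
#' @export
make_roi_masks <- function(grid, thickness_mm = 5) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  nthick <- ceiling(thickness_mm / grid$voxel_size[3])
  z0 <- floor((nz - nthick) / 2) + 1L
  zi <- z0:(z0 + nthick - 1L)
  yi <- (floor(ny * 0.375) + 1L):ceiling(ny * 0.625)
  assoc_x <- (floor(nx * 0.150) + 1L):floor(nx * 0.250)
  proj_x <- (floor(nx * 0.300) + 1L):floor(nx * 0.400)
  if (nz < nthick || length(yi) < 1L || length(assoc_x) < 1L ||
      length(proj_x) < 1L || max(proj_x) > floor(nx / 2) ||
      min(proj_x) <= max(assoc_x)) {
    stop("grid too small to place four disjoint fiber ROI slabs", call. = FALSE)
  }
  slab <- function(xi) {
    m <- array(FALSE, dim = grid$shape)
    m[xi, yi, zi] <- TRUE
    m
  }
  mirror_x <- function(xi) nx + 1L - rev(xi)
  structure(
    list(proj_left = slab(proj_x),
         proj_right = slab(mirror_x(proj_x)),
         assoc_left = slab(assoc_x),
         assoc_right = slab(mirror_x(assoc_x)),
         grid = grid),
    class = "roi_mask_set"
  )
}

roi_mask_names <- c("proj_left", "proj_right", "assoc_left", "assoc_right")

#' Per-voxel diffusion tensor volume
#'
#' Stores the six unique elements of the symmetric tensor (mm^2/s) per voxel
#' in component order `xx, yy, zz, xy, xz, yz`.
#'
#' @param values 4D array, `grid$shape` x 6.
#' @param grid A [volume_grid()].
#' @return A `tensor_volume`.
#' @export
tensor_volume <- function(values, grid) {
  values <- as.array(values)
  if (length(dim(values)) != 4L || !all(dim(values)[1:3] == grid$shape) ||
      dim(values)[4] != 6L) {
    stop("`values` must be shape x 6 (xx, yy, zz, xy, xz, yz)", call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "tensor_volume")
}

tensor_component_index <- c(xx = 1L, yy = 2L, zz = 3L, xy = 4L, xz = 5L, yz = 6L)

#' @rdname tensor_volume
#' @param tensor A `tensor_volume`.
#' @param component One of `"xx"`, `"yy"`, `"zz"`, `"xy"`, `"xz"`, `"yz"`.
#' @export
tensor_component <- function(tensor, component) {
  k <- tensor_component_index[[match.arg(component, names(tensor_component_index))]]
  array(tensor$values[, , , k], dim = tensor$grid$shape)
}

#' Noiseless tensor field realizing a target ALPS value
#'
#' Forward model of the ALPS construct. Background voxels are isotropic at
#' `d_background`. In projection-fiber ROIs the fiber axis is z and in
#' association-fiber ROIs it is y; in both, the perpendicular diffusivity the
#' index penalizes (Dyy in projection, Dzz in association ROIs) is `d_perp`
#' and the perivascular-direction Dxx (and the fiber-axis diffusivity) is
#' `latent_alps * d_perp`. The ROI-mean ALPS of the field therefore equals
#' `latent_alps` exactly, and `latent_alps = 1` gives isotropic ROI tensors.
#'
#' @param latent_alps Target ALPS value (> 0).
#' @param masks A `roi_mask_set` from [make_roi_masks()].
#' @param d_perp,d_background,diffusivity_range See [synth_params()].
#' @return A [tensor_volume()].
#' @export
simulate_tensor_field <- function(latent_alps, masks, d_perp = 0.6e-3,
                                  d_background = 0.7e-3,
                                  diffusivity_range = c(1e-4, 3.5e-3)) {
  if (!is.finite(latent_alps) || latent_alps <= 0) {
    stop("latent_alps must be > 0", call. = FALSE)
  }
  d_x <- latent_alps * d_perp
  used <- c(d_x, d_perp, d_background)
  if (any(used < diffusivity_range[1] | used > diffusivity_range[2])) {
    stop(sprintf(
      "requested latent_alps %.3g needs diffusivity %.3g mm^2/s outside the physiological range [%g, %g]",
      latent_alps, d_x, diffusivity_range[1], diffusivity_range[2]),
      call. = FALSE)
  }
  grid <- masks$grid
  vals <- array(0, dim = c(grid$shape, 6L))
  vals[, , , 1:3] <- d_background
  proj <- masks$proj_left | masks$proj_right
  assoc <- masks$assoc_left | masks$assoc_right
  dxx <- array(vals[, , , 1], grid$shape)
  dyy <- array(vals[, , , 2], grid$shape)
  dzz <- array(vals[, , , 3], grid$shape)
  dxx[proj] <- d_x; dyy[proj] <- d_perp; dzz[proj] <- d_x
  dxx[assoc] <- d_x; dyy[assoc] <- d_x; dzz[assoc] <- d_perp
  vals[, , , 1] <- dxx; vals[, , , 2] <- dyy; vals[, , , 3] <- dzz
  tensor_volume(vals, grid)
}

#' Forward-simulate a diffusion-weighted stack
#'
#' Evaluates the monoexponential tensor signal model
#' `S_i = s0 * exp(-b_i * g_i' D g_i)` per gradient, with optional additive
#' Gaussian or magnitude (Rician) noise.
#'
#' @param tensor A [tensor_volume()].
#' @param gtab Gradient table from [make_gradient_table()].
#' @param s0 Unweighted signal (> 0).
#' @param noise_sd Noise SD in signal units (>= 0).
#' @param noise_model `"none"`, `"gaussian"` or `"rician"`.
#' @param seed Integer seed used when noise is drawn.
#' @return A `dwi_stack`: 4D array (grid shape x frames) with the grid and
#'   gradient table attached.
#' @export
simulate_dwi <- function(tensor, gtab, s0 = 1000, noise_sd = 0,
                         noise_model = c("none", "gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  grid <- tensor$grid
  nvox <- prod(grid$shape)
  V <- matrix(tensor$values, nrow = nvox, ncol = 6L)
  # quadratic form coefficients per frame: b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz)
  Q <- with(gtab, cbind(gx^2, gy^2, gz^2, 2 * gx * gy, 2 * gx * gz, 2 * gy * gz) * b)
  signal <- s0 * exp(-(V %*% t(Q)))
  if (noise_model != "none" && noise_sd > 0) {
    signal <- withr::with_seed(as.integer(seed), {
      n <- length(signal)
      if (noise_model == "gaussian") {
        signal + stats::rnorm(n, 0, noise_sd)
      } else {
        sqrt((signal + stats::rnorm(n, 0, noise_sd))^2 +
               stats::rnorm(n, 0, noise_sd)^2)
      }
    })
  }
  structure(
    list(values = array(signal, dim = c(grid$shape, nrow(gtab))),
         grid = grid, gtab = gtab),
    class = "dwi_stack"
  )
}

subject_seed <- function(run_seed, i, stream = 0L) {
  as.integer((as.numeric(run_seed) + 100003 * i + 7919 * stream) %% 2147483647)
}

sphere_region <- function(grid, center_mm, radius_mm) {
  sphere_mask(center_mm, radius_mm, grid)$mask
}

brain_ellipsoid <- function(grid, fraction = 0.85) {
  half_fov <- grid$voxel_size * (grid$shape - 1L) / 2
  semi <- fraction * half_fov
  ijk <- as.matrix(expand.grid(i = seq_len(grid$shape[1]) - 1L,
                               j = seq_len(grid$shape[2]) - 1L,
                               k = seq_len(grid$shape[3]) - 1L))
  xyz <- voxel_to_world(grid, ijk)
  inside <- (xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 +
    (xyz[, 3] / semi[3])^2 <= 1
  array(inside, dim = grid$shape)
}

# Deterministic per-subject GM map: brain ellipsoid background, the two
# designated coherent regions, plus voxelwise white noise (seeded).
subject_gm_volume <- function(params, x, m, sseed, scaffold) {
  g <- params$gm
  vals <- array(0, dim = params$grid$shape)
  vals[scaffold$brain] <- g$background
  vals[scaffold$seed_region] <- m / scaffold$region_volume_mm3
  vals[scaffold$coupled_region] <- g$background +
    params$gm_coupling * (x - params$alps_mean_ctl)
  noise <- withr::with_seed(sseed, stats::rnorm(sum(scaffold$brain), 0, g$noise_sd))
  vals[scaffold$brain] <- vals[scaffold$brain] + noise
  vals[vals < 0] <- 0
  scalar_volume(vals, params$grid)
}

gm_scaffold <- function(params) {
  grid <- params$grid
  seed_region <- sphere_region(grid, params$gm$seed_center_mm,
                               params$gm$region_radius_mm)
  coupled_region <- sphere_region(grid, params$gm$coupled_center_mm,
                                  params$gm$region_radius_mm)
  brain <- brain_ellipsoid(grid, params$gm$brain_fraction)
  brain <- brain | seed_region | coupled_region
  list(brain = brain, seed_region = seed_region,
       coupled_region = coupled_region,
       region_volume_mm3 = sum(seed_region) * voxel_volume(grid))
}

# Theoretical CTL-group SD of the raw latent outcome Y, used to calibrate
# printed cognitive scales deterministically (not from the sample).
raw_outcome_sd <- function(params) {
  md <- params$mediation
  vx <- params$alps_sd^2
  sqrt(md$c_prime^2 * vx + md$b^2 * (md$a^2 * vx + md$sd_m^2) +
         2 * md$c_prime * md$b * md$a * vx + md$sd_y^2)
}

#' Simulate a complete synthetic cohort
#'
#' Draws the full two-group cohort: latent ALPS `X` per subject (group mean
#' plus Gaussian noise), mediator `M` (true seed-region GM volume,
#' `m0 + a*(X - ctl mean) + noise`), latent outcome
#' `Y = c'*(X - ctl mean) + b*(M - m0) + noise`, covariates, and the printed
#' cognitive scores (each an affine recalibration of `Y` to its control-group
#' mean/SD with independent residual noise, clipped into its valid range;
#' clipping is logged). Per-subject volumes are a noiseless tensor field
#' realizing `X` and a GM map whose designated left-hemisphere region
#' integrates to `M` (the mediation seed) and whose right-hemisphere region
#' intensity follows `gm_coupling * X`.
#'
#' @param params A [synth_params()].
#' @param keep_volumes If `TRUE`, return per-subject tensor and GM volumes in
#'   `$subjects`; with large cohorts set `FALSE` and regenerate volumes on
#'   demand via the returned `$volume_fn`.
#' @return A list of class `synth_cohort`: `cohort` (tibble with covariates
#'   and scores), `truth` (tibble with `x`, `m`, `y_raw` per subject),
#'   `masks` (ROI slabs), `regions` (designated GM region masks), `grid`,
#'   `params`, `volume_fn(i)` and optionally `subjects`.
#' @export
simulate_subjects <- function(params, keep_volumes = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  md <- params$mediation
  n <- params$n_ctl + params$n_yoad
  group <- c(rep("CTL", params$n_ctl), rep("YOAD", params$n_yoad))
  scaffold <- gm_scaffold(params)
  info <- cognitive_score_info()
  cohort <- withr::with_seed(params$seed, {
    mu <- ifelse(group == "YOAD",
                 params$alps_mean_ctl + params$alps_shift_yoad,
                 params$alps_mean_ctl)
    x <- pmin(pmax(stats::rnorm(n, mu, params$alps_sd), 0.2), 5)
    m <- md$m0 + md$a * (x - params$alps_mean_ctl) + stats::rnorm(n, 0, md$sd_m)
    y_raw <- md$c_prime * (x - params$alps_mean_ctl) + md$b * (m - md$m0) +
      stats::rnorm(n, 0, md$sd_y)
    z <- y_raw / raw_outcome_sd(params)
    cv <- params$covariates
    age <- ifelse(group == "YOAD",
                  stats::rnorm(n, cv$age$yoad[1], cv$age$yoad[2]),
                  stats::rnorm(n, cv$age$ctl[1], cv$age$ctl[2]))
    edu <- pmax(0, ifelse(group == "YOAD",
                          stats::rnorm(n, cv$education$yoad[1], cv$education$yoad[2]),
                          stats::rnorm(n, cv$education$ctl[1], cv$education$ctl[2])))
    sex <- ifelse(stats::runif(n) < ifelse(group == "YOAD",
                                           cv$female_prop$yoad,
                                           cv$female_prop$ctl), "F", "M")
    etiv <- stats::rnorm(n, cv$etiv[1], cv$etiv[2])
    tab <- tibble::tibble(
      id = sprintf("S%03d", seq_len(n)), group = group,
      age = age, education = edu, sex = sex, etiv = etiv
    )
    lam <- params$score_loading
    n_clipped <- 0L
    for (k in seq_len(nrow(info))) {
      zk <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
      raw <- info$ctl_mean[k] + info$ctl_sd[k] * zk
      clipped <- pmin(pmax(raw, 0), info$max[k])
      n_clipped <- n_clipped + sum(clipped != raw)
      tab[[info$test[k]]] <- clipped
    }
    attr(tab, "n_clipped") <- n_clipped
    attr(tab, "truth") <- tibble::tibble(
      id = tab$id, group = group, x = x, m = m, y_raw = y_raw
    )
    tab
  })
  truth <- attr(cohort, "truth")
  n_clipped <- attr(cohort, "n_clipped")
  attr(cohort, "truth") <- NULL
  attr(cohort, "n_clipped") <- NULL
  if (n_clipped > 0) {
    message(n_clipped, " score value(s) clipped into their printed range")
  }
  masks <- make_roi_masks(params$grid)
  volume_fn <- function(i, what = c("tensor", "gm")) {
    what <- match.arg(what)
    if (what == "tensor") {
      simulate_tensor_field(truth$x[i], masks, params$d_perp,
                            params$d_background, params$diffusivity_range)
    } else {
      subject_gm_volume(params, truth$x[i], truth$m[i],
                        subject_seed(params$seed, i, 1L), scaffold)
    }
  }
  out <- list(cohort = cohort, truth = truth, masks = masks,
              regions = scaffold, grid = params$grid, params = params,
              volume_fn = volume_fn)
  if (keep_volumes) {
    out$subjects <- lapply(seq_len(n), function(i) {
      list(tensor = volume_fn(i, "tensor"), gm = volume_fn(i, "gm"))
    })
  }
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", sum(x$cohort$group == "YOAD"), " YOAD + ",
      sum(x$cohort$group == "CTL"), " CTL subjects\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.tsv` and `truth.tsv`, the four fiber ROI masks and the
#' designated GM region masks as NIfTI, `bvals`/`bvecs` text files for the
#' configured gradient table, and optionally per-subject GM/tensor volumes.
#'
#' @param sim A `synth_cohort` from [simulate_subjects()].
#' @param dir Output directory (created if needed).
#' @param n_subject_volumes Number of subjects whose GM map and tensor
#'   component maps are written as NIfTI (0 = none; volumes are regenerable
#'   from `sim$volume_fn`).
#' @return `dir`, invisibly.
#' @export
write_synth_cohort <- function(sim, dir, n_subject_volumes = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$cohort, file.path(dir, "cohort.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  for (nm in roi_mask_names) {
    write_volume(scalar_volume(sim$masks[[nm]] * 1, sim$grid),
                 file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  write_volume(scalar_volume(sim$regions$seed_region * 1, sim$grid),
               file.path(dir, "region_seed.nii.gz"))
  write_volume(scalar_volume(sim$regions$coupled_region * 1, sim$grid),
               file.path(dir, "region_coupled.nii.gz"))
  gtab <- make_gradient_table(sim$params$dwi$n_directions,
                              sim$params$dwi$b_value, sim$params$dwi$n_b0)
  writeLines(paste(format(gtab$b, trim = TRUE), collapse = " "),
             file.path(dir, "bvals"))
  writeLines(c(paste(format(gtab$gx, trim = TRUE), collapse = " "),
               paste(format(gtab$gy, trim = TRUE), collapse = " "),
               paste(format(gtab$gz, trim = TRUE), collapse = " ")),
             file.path(dir, "bvecs"))
  for (i in seq_len(min(n_subject_volumes, nrow(sim$cohort)))) {
    write_volume(sim$volume_fn(i, "gm"),
                 file.path(dir, sprintf("%s_gm.nii.gz", sim$cohort$id[i])))
    tv <- sim$volume_fn(i, "tensor")
    for (comp in c("xx", "yy", "zz")) {
      write_volume(scalar_volume(tensor_component(tv, comp), sim$grid),
                   file.path(dir, sprintf("%s_d%s.nii.gz", sim$cohort$id[i], comp)))
    }
  }
  invisible(dir)
}
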