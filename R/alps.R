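#' Fit diffusion tensors by (weighted) log-linear least squares
#'
#' Per voxel, solves `log(S_i) = log(S0) - b_i * g_i' D g_i` for the six
#' tensor elements and `log(S0)`. Weighted least squares with weights equal
#' to the squared observed signals (standard WLS for the log-transformed
#' model) is the default; ordinary least squares is available. Voxels inside
#' the mask with any non-positive signal are excluded from the fit and
#' counted (QC message); voxels outside the mask are left as `NA`.
#'
#' @param dwi A `dwi_stack` from [simulate_dwi()], or a 4D array.
#' @param gtab Gradient table (tibble `gx`, `gy`, `gz`, `b`); taken from the
#'   stack when omitted.
#' @param mask Logical array of voxels to fit (default: all).
#' @param method `"wls"` (default) or `"ols"`.
#' @return A [tensor_volume()] with `NA` outside the fitted set.
#' @export
fit_tensor <- function(dwi, gtab = NULL, mask = NULL,
                       method = c("wls", "ols")) {
  method <- match.arg(method)
  if (inherits(dwi, "dwi_stack")) {
    if (is.null(gtab)) gtab <- dwi$gtab
    grid <- dwi$grid
    vals <- dwi$values
  } else {
    vals <- as.array(dwi)
    if (is.null(gtab)) stop("`gtab` required for a bare array", call. = FALSE)
    grid <- volume_grid(dim(vals)[1:3])
  }
  nframes <- dim(vals)[4]
  if (nrow(gtab) != nframes) {
    stop("gradient table rows must match DWI frames", call. = FALSE)
  }
  if (!any(gtab$b == 0)) stop("need >= 1 b = 0 frame", call. = FALSE)
  dwi_rows <- gtab$b > 0
  g <- gtab[dwi_rows, ]
  norms <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  if (any(abs(norms - 1) > 1e-8)) {
    stop("diffusion-weighted directions must be unit vectors", call. = FALSE)
  }
  X <- with(gtab, cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
                        -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz))
  if (qr(X)$rank < 7L) {
    stop("rank-deficient gradient design: need >= 6 non-collinear directions",
         call. = FALSE)
  }
  nvox <- prod(grid$shape)
  S <- matrix(vals, nrow = nvox, ncol = nframes)
  if (is.null(mask)) mask <- array(TRUE, dim = grid$shape)
  fit_idx <- which(as.vector(mask))
  pos <- rowSums(S[fit_idx, , drop = FALSE] <= 0) == 0L
  n_excluded <- sum(!pos)
  if (n_excluded > 0) {
    message(n_excluded, " voxel(s) with non-positive signal excluded from the tensor fit")
  }
  fit_idx <- fit_idx[pos]
  if (length(fit_idx) == 0L) stop("no voxels with positive signals in mask", call. = FALSE)
  B <- matrix(NA_real_, nrow = nvox, ncol = 7L)
  Y <- log(S[fit_idx, , drop = FALSE])
  if (method == "ols") {
    XtXinvXt <- solve(crossprod(X), t(X))
    B[fit_idx, ] <- Y %*% t(XtXinvXt)
  } else {
    W <- S[fit_idx, , drop = FALSE]  # sqrt of weights S^2
    for (r in seq_along(fit_idx)) {
      w <- W[r, ]
      B[fit_idx[r], ] <- .lm.fit(X * w, Y[r, ] * w)$coefficients
    }
  }
  out <- tensor_volume(array(B[, 2:7], dim = c(grid$shape, 6L)), grid)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Fractional anisotropy map
#'
#' `FA = sqrt(3/2) * ||D - MD*I||_F / ||D||_F`, computed from rotationally
#' invariant tensor norms (identical to the eigenvalue formula). Degenerate
#' all-zero tensors yield FA = 0 by convention.
#'
#' @param tensor A [tensor_volume()].
#' @return A [scalar_volume()] with FA in `[0, 1]` for positive-definite
#'   tensors, `NA` where the tensor is undefined.
#' @export
fractional_anisotropy <- function(tensor) {
  v <- tensor$values
  dxx <- v[, , , 1]; dyy <- v[, , , 2]; dzz <- v[, , , 3]
  dxy <- v[, , , 4]; dxz <- v[, , , 5]; dyz <- v[, , , 6]
  md <- (dxx + dyy + dzz) / 3
  off2 <- 2 * (dxy^2 + dxz^2 + dyz^2)
  dev2 <- (dxx - md)^2 + (dyy - md)^2 + (dzz - md)^2 + off2
  nrm2 <- dxx^2 + dyy^2 + dzz^2 + off2
  fa <- sqrt(1.5 * dev2 / nrm2)
  fa[nrm2 == 0] <- 0
  scalar_volume(array(fa, dim = tensor$grid$shape), tensor$grid)
}

resample_mask_nn <- function(mask, mask_grid, target_grid, transform = NULL) {
  ijk <- as.matrix(expand.grid(i = seq_len(target_grid$shape[1]) - 1L,
                               j = seq_len(target_grid$shape[2]) - 1L,
                               k = seq_len(target_grid$shape[3]) - 1L))
  xyz <- voxel_to_world(target_grid, ijk)
  if (!is.null(transform)) {
    transform <- as.matrix(transform)
    det3 <- det(transform[1:3, 1:3])
    if (!is.finite(det3) || abs(det3) < .Machine$double.eps) {
      stop("non-invertible transform", call. = FALSE)
    }
    xyz <- cbind(xyz, 1) %*% t(transform)
    xyz <- xyz[, 1:3, drop = FALSE]
  }
  src <- round(world_to_voxel(mask_grid, xyz)) + 1L
  ok <- src[, 1] >= 1L & src[, 1] <= mask_grid$shape[1] &
    src[, 2] >= 1L & src[, 2] <= mask_grid$shape[2] &
    src[, 3] >= 1L & src[, 3] <= mask_grid$shape[3]
  out <- rep(FALSE, nrow(src))
  out[ok] <- mask[src[ok, , drop = FALSE]]
  array(out, dim = target_grid$shape)
}

#' ROI-mean directional diffusivities
#'
#' Arithmetic mean of Dxx, Dyy and Dzz over each fiber ROI, per hemisphere.
#' When the masks live on a different grid than the tensor (template vs
#' subject space), they are transported by nearest-neighbour resampling under
#' the optional template-from-subject affine `transform` (maps subject-grid
#' world mm into mask-grid world mm).
#'
#' @param tensor A [tensor_volume()].
#' @param masks A `roi_mask_set`.
#' @param transform Optional 4x4 affine; identity when omitted.
#' @return A tibble with one row per side and columns `dxx_proj`, `dyy_proj`,
#'   `dzz_proj`, `dxx_assoc`, `dyy_assoc`, `dzz_assoc` (mm^2/s).
#' @export
roi_mean_diffusivities <- function(tensor, masks, transform = NULL) {
  same_grid <- is.null(transform) && grids_equal(masks$grid, tensor$grid)
  get_mask <- function(nm) {
    m <- masks[[nm]]
    if (same_grid) return(m)
    m <- resample_mask_nn(m, masks$grid, tensor$grid, transform)
    n <- sum(m)
    if (n == 0L) stop("ROI mask '", nm, "' empty after resampling", call. = FALSE)
    if (n < 10L) warning("ROI mask '", nm, "' has only ", n,
                         " voxels after resampling", call. = FALSE)
    m
  }
  comp <- function(what) tensor_component(tensor, what)
  dxx <- comp("xx"); dyy <- comp("yy"); dzz <- comp("zz")
  row_for <- function(side) {
    pm <- get_mask(paste0("proj_", side))
    am <- get_mask(paste0("assoc_", side))
    tibble::tibble(
      side = side,
      dxx_proj = mean(dxx[pm]), dyy_proj = mean(dyy[pm]), dzz_proj = mean(dzz[pm]),
      dxx_assoc = mean(dxx[am]), dyy_assoc = mean(dyy[am]), dzz_assoc = mean(dzz[am])
    )
  }
  dplyr::bind_rows(row_for("left"), row_for("right"))
}

#' ALPS index from ROI-mean diffusivities
#'
#' Per hemisphere, `ALPS = mean(Dxxproj, Dxxassoc) / mean(Dyyproj, Dzzassoc)`
#' (the x-axis is the perivascular direction; Dyy in the projection ROI and
#' Dzz in the association ROI are the diffusivities perpendicular to the
#' fibers that the index penalizes). The bilateral value is the mean of the
#' two sides. Dzzproj and Dyyassoc are recorded upstream but do not enter
#' the formula.
#'
#' @param means Tibble from [roi_mean_diffusivities()] with rows `left` and
#'   `right`.
#' @return A one-row tibble: `alps_left`, `alps_right`, `alps_bilateral`.
#' @export
alps_index <- function(means) {
  need <- c("side", "dxx_proj", "dyy_proj", "dxx_assoc", "dzz_assoc")
  if (!all(need %in% names(means))) {
    stop("`means` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  one_side <- function(side) {
    r <- means[means$side == side, ]
    if (nrow(r) != 1L) stop("need exactly one row for side '", side, "'", call. = FALSE)
    denom <- mean(c(r$dyy_proj, r$dzz_assoc))
    if (!is.finite(denom) || denom <= 0) {
      stop("non-positive ALPS denominator mean(Dyyproj, Dzzassoc) on the ",
           side, " side", call. = FALSE)
    }
    mean(c(r$dxx_proj, r$dxx_assoc)) / denom
  }
  left <- one_side("left")
  right <- one_side("right")
  tibble::tibble(alps_left = left, alps_right = right,
                 alps_bilateral = mean(c(left, right)))
}

#' One-call ALPS computation for a tensor volume
#'
#' Convenience wrapper: ROI means plus index, as a single wide row suitable
#' for per-subject binding.
#'
#' @inheritParams roi_mean_diffusivities
#' @return A one-row tibble: the six diffusivities per side (suffixed
#'   `_left`/`_right`) and `alps_left`, `alps_right`, `alps_bilateral`.
#' @export
compute_alps <- function(tensor, masks, transform = NULL) {
  means <- roi_mean_diffusivities(tensor, masks, transform)
  wide <- tidyr::pivot_wider(
    means,
    names_from = "side",
    values_from = !dplyr::all_of("side"),
    names_glue = "{.value}_{side}"
  )
  dplyr::bind_cols(wide, alps_index(means))
}
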