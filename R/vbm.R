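#' Gaussian smoothing of a volume
#'
#' Separable Gaussian smoothing with the kernel width given as full width at
#' half maximum in mm, converted per axis to
#' `sigma = fwhm / (voxel_size * 2*sqrt(2*log(2)))` voxels. The kernel is
#' truncated at 4 sigma and normalized, with zero padding at the edges, so
#' total intensity is conserved for interior-supported input.
#'
#' @param vol A [scalar_volume()].
#' @param fwhm_mm Full width at half maximum, mm (>= 0; 0 = identity).
#' @return A smoothed [scalar_volume()].
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  out <- smooth_array(vol$values, fwhm_mm, vol$grid$voxel_size)
  scalar_volume(out, vol$grid)
}

fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
}

smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + r + 1]
  }
  K
}

smooth_array <- function(a, fwhm_mm, voxel_size) {
  d <- dim(a)
  sig <- fwhm_to_sigma(fwhm_mm, voxel_size)
  # axis 1
  a <- array(smoothing_matrix(d[1], sig[1]) %*% matrix(a, d[1]), dim = d)
  # axis 2
  a <- aperm(a, c(2, 1, 3))
  a <- array(smoothing_matrix(d[2], sig[2]) %*% matrix(a, d[2]), dim = d[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  a <- aperm(a, c(3, 1, 2))
  a <- array(smoothing_matrix(d[3], sig[3]) %*% matrix(a, d[3]), dim = d[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}

#' Stack gray-matter volumes into a subjects-by-voxels matrix
#'
#' @param gm A list of [scalar_volume()]s on a shared grid (one per subject),
#'   or an already-built numeric matrix with a `grid` attribute.
#' @return A matrix `n_subjects x n_voxels` with attribute `grid`.
#' @export
gm_matrix <- function(gm) {
  if (is.matrix(gm)) {
    if (is.null(attr(gm, "grid"))) stop("matrix input needs a 'grid' attribute", call. = FALSE)
    return(gm)
  }
  stopifnot(length(gm) > 0, inherits(gm[[1]], "scalar_volume"))
  grid <- gm[[1]]$grid
  Y <- matrix(NA_real_, nrow = length(gm), ncol = prod(grid$shape))
  for (i in seq_along(gm)) {
    if (!grids_equal(gm[[i]]$grid, grid)) stop("GM volumes on mismatched grids", call. = FALSE)
    Y[i, ] <- as.vector(gm[[i]]$values)
  }
  attr(Y, "grid") <- grid
  Y
}

#' Default voxel analysis mask
#'
#' Voxels whose cohort-mean GM exceeds 10% of the grand mean of the mean
#' image — a standard implicit-mask heuristic for modulated GM.
#'
#' @param Y Subjects-by-voxels matrix from [gm_matrix()].
#' @return A logical 3D array.
#' @export
gm_analysis_mask <- function(Y) {
  grid <- attr(Y, "grid")
  mvol <- colMeans(Y)
  array(mvol > 0.1 * mean(mvol), dim = grid$shape)
}

#' Build a design matrix for the voxelwise GLM
#'
#' Thin wrapper over [stats::model.matrix()] keeping the cohort tibble
#' workflow: rows follow `data`, the first column is the intercept.
#'
#' @param data Cohort tibble (one row per subject, in volume order).
#' @param formula RHS formula, e.g. `~ group + etiv`.
#' @return Numeric design matrix with column names.
#' @export
design_matrix <- function(data, formula) {
  X <- stats::model.matrix(formula, data = data)
  if (nrow(X) != nrow(data)) {
    stop("design rows dropped (missing values?); complete cases required here",
         call. = FALSE)
  }
  X
}

resolve_contrast <- function(design, contrast) {
  if (is.character(contrast)) {
    if (!contrast %in% colnames(design)) {
      stop("contrast column '", contrast, "' not in design", call. = FALSE)
    }
    cvec <- as.numeric(colnames(design) == contrast)
  } else {
    cvec <- as.numeric(contrast)
  }
  if (length(cvec) != ncol(design)) {
    stop("contrast length must equal design column count", call. = FALSE)
  }
  if (all(cvec == 0)) stop("contrast is all zero", call. = FALSE)
  cvec
}

#' Mass-univariate voxelwise GLM
#'
#' Fits the same ordinary-least-squares linear model at every in-mask voxel
#' (GM value as response) and returns the T statistic for a single contrast,
#' with two-sided Student-t p-values available downstream at
#' `df = n - rank(design)`. Voxels with zero residual variance and zero
#' effect (e.g. constant GM) get T = 0 and are counted.
#'
#' @param gm List of [scalar_volume()]s or a [gm_matrix()] matrix.
#' @param design Numeric design matrix (subjects x terms), full column rank.
#' @param contrast Column name or numeric vector selecting the effect.
#' @param mask Optional logical array; default [gm_analysis_mask()].
#' @return A `stat_map`: list with 3D `t`, `df`, `mask`, `grid`, `contrast`.
#' @export
voxelwise_glm <- function(gm, design, contrast, mask = NULL) {
  Y <- gm_matrix(gm)
  grid <- attr(Y, "grid")
  design <- as.matrix(design)
  if (nrow(design) != nrow(Y)) {
    stop("one GM volume per design row required", call. = FALSE)
  }
  qrX <- qr(design)
  p <- ncol(design)
  if (qrX$rank < p) stop("rank-deficient design matrix", call. = FALSE)
  n <- nrow(design)
  if (n < p + 2L) stop("need at least rank + 2 subjects", call. = FALSE)
  cvec <- resolve_contrast(design, contrast)
  if (is.null(mask)) mask <- gm_analysis_mask(Y)
  vidx <- which(as.vector(mask))
  Ym <- Y[, vidx, drop = FALSE]
  XtXinv <- chol2inv(qr.R(qrX))
  a <- design %*% (XtXinv %*% cvec)          # effect = a' y
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)  # c'(X'X)^-1 c
  eff <- drop(crossprod(a, Ym))
  Q <- qr.Q(qrX)
  # residuals computed explicitly: the sum-of-squares shortcut cancels
  # catastrophically for near-perfect fits
  rss <- colSums((Ym - Q %*% crossprod(Q, Ym))^2)
  df <- n - p
  s2 <- pmax(rss, 0) / df
  se <- sqrt(cvar * s2)
  tstat <- eff / se
  degenerate <- se == 0
  tstat[degenerate] <- 0
  tvol <- array(NA_real_, dim = grid$shape)
  tvol[vidx] <- tstat
  structure(
    list(t = tvol, df = df, mask = mask, grid = grid, contrast = cvec,
         n = n, n_degenerate = sum(degenerate)),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> df = ", x$df, ", ", sum(x$mask), " in-mask voxels, max |T| = ",
      signif(max(abs(x$t), na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Uncorrected p-value map for a stat map
#'
#' @param stat A `stat_map`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A [scalar_volume()] of Student-t p-values (`NA` outside mask).
#' @export
stat_map_p <- function(stat, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(stat$t), stat$df, lower.tail = FALSE),
    greater = stats::pt(stat$t, stat$df, lower.tail = FALSE),
    less = stats::pt(stat$t, stat$df)
  )
  scalar_volume(array(p, dim = stat$grid$shape), stat$grid)
}

#' Family-wise-error corrected p-map by max-statistic permutation
#'
#' Controls the family-wise error across voxels with the permutation
#' distribution of the maximum |T|. Exchangeability under the null is
#' obtained by Freedman-Lane residual permutation: the response is reduced
#' against the nuisance columns (those with zero contrast weight), the
#' reduced-model residuals are permuted, refitted under the full model, and
#' the maximum |T| recorded per permutation. The corrected p at voxel v is
#' `(1 + #{perm : maxT >= |T_obs(v)|}) / (1 + n_perm)`. For a group contrast
#' with an intercept-only nuisance this reduces to label permutation.
#'
#' @inheritParams voxelwise_glm
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return A [scalar_volume()] of corrected p-values with attributes
#'   `stat_map` (the observed map) and `max_t` (the permutation
#'   distribution).
#' @export
fwe_threshold_maxT <- function(gm, design, contrast, n_perm = 499L,
                               seed = 1L, mask = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  Y <- gm_matrix(gm)
  grid <- attr(Y, "grid")
  design <- as.matrix(design)
  cvec <- resolve_contrast(design, contrast)
  if (is.null(mask)) mask <- gm_analysis_mask(Y)
  obs <- voxelwise_glm(Y, design, cvec, mask = mask)
  vidx <- which(as.vector(mask))
  Ym <- Y[, vidx, drop = FALSE]
  n <- nrow(design)
  Z <- design[, cvec == 0, drop = FALSE]
  if (ncol(Z) == 0L) Z <- matrix(1, n, 1L)
  qrZ <- qr(Z)
  Fit <- qr.fitted(qrZ, Ym)
  Res <- Ym - Fit
  qrX <- qr(design)
  p <- ncol(design)
  XtXinv <- chol2inv(qr.R(qrX))
  a <- design %*% (XtXinv %*% cvec)
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  Q <- qr.Q(qrX)
  df <- n - p
  max_t <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      Yb <- Fit + Res[sample.int(n), , drop = FALSE]
      eff <- drop(crossprod(a, Yb))
      rss <- colSums(Yb^2) - colSums(crossprod(Q, Yb)^2)
      se <- sqrt(cvar * pmax(rss, 0) / df)
      tb <- eff / se
      tb[se == 0] <- 0
      max(abs(tb))
    }, numeric(1))
  })
  t_obs <- abs(obs$t[vidx])
  p_corr <- (1 + vapply(t_obs, function(t0) sum(max_t >= t0), numeric(1))) /
    (1 + n_perm)
  pvol <- array(NA_real_, dim = grid$shape)
  pvol[vidx] <- p_corr
  out <- scalar_volume(pvol, grid)
  attr(out, "stat_map") <- obs
  attr(out, "max_t") <- max_t
  out
}

connectivity_offsets <- function(connectivity = 18L) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
    "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1,
    stop("connectivity must be 6, 18 or 26", call. = FALSE))
  d[keep, , drop = FALSE]
}

# Connected-component labeling by iterative minimum-label propagation.
label_components <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- seq_len(sum(mask))
  offs <- connectivity_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      sx <- seq(max(1, 1 + o[1]), min(d[1], d[1] + o[1]))
      sy <- seq(max(1, 1 + o[2]), min(d[2], d[2] + o[2]))
      sz <- seq(max(1, 1 + o[3]), min(d[3], d[3] + o[3]))
      tx <- sx - o[1]; ty <- sy - o[2]; tz <- sz - o[3]
      src <- lab[sx, sy, sz, drop = FALSE]
      tgt <- new[tx, ty, tz, drop = FALSE]
      both <- src > 0 & tgt > 0
      tgt[both] <- pmin(tgt[both], src[both])
      new[tx, ty, tz] <- tgt
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  relab <- array(0L, dim = d)
  relab[lab > 0] <- match(lab[lab > 0], ids)
  relab
}

supra_threshold <- function(stat, p_voxel, alternative, p_map = NULL) {
  score <- switch(alternative,
    greater = stat$t, less = -stat$t, two.sided = abs(stat$t))
  if (is.null(p_map)) {
    tcrit <- stats::qt(if (alternative == "two.sided") 1 - p_voxel / 2 else 1 - p_voxel,
                       stat$df)
    supra <- !is.na(score) & score > tcrit & stat$mask
  } else {
    pv <- if (inherits(p_map, "scalar_volume")) p_map$values else p_map
    supra <- !is.na(score) & !is.na(pv) & pv < p_voxel & score > 0 & stat$mask
  }
  list(supra = supra, score = score)
}

#' Cluster-extent thresholded peak table
#'
#' Thresholds the stat map at a voxel-forming p-value, labels supra-threshold
#' voxels into connected components (18-connectivity by default), drops
#' components not exceeding the extent threshold (strict `size > min_extent`),
#' and reports up to three local maxima per cluster separated by at least
#' `peak_sep_mm`, with world (template) coordinates in mm.
#'
#' @param stat A `stat_map` from [voxelwise_glm()].
#' @param p_voxel Voxel-forming threshold on the p-value (default 0.001).
#' @param min_extent Extent threshold in voxels; clusters must exceed it
#'   (default 100, i.e. size >= 101).
#' @param peak_sep_mm Minimum separation between reported peaks (default 8).
#' @param labels Optional [scalar_volume()] of integer anatomy labels
#'   sampled at each peak.
#' @param alternative Direction of the voxel-forming test: `"greater"`
#'   (T above the upper-tail critical value; default), `"less"`, or
#'   `"two.sided"`.
#' @param connectivity 6, 18 or 26.
#' @param p_map Optional [scalar_volume()] of p-values (e.g. an
#'   FWE-corrected map from [fwe_threshold_maxT()]); when given, voxels with
#'   `p_map < p_voxel` (and positive score direction) form clusters instead
#'   of the parametric threshold.
#' @return A tibble (possibly empty): `cluster`, `size`, `label`,
#'   `laterality`, `x`, `y`, `z`, `t`, `p` (uncorrected, per
#'   `alternative`), sorted by descending cluster peak T.
#' @export
cluster_table <- function(stat, p_voxel = 0.001, min_extent = 100L,
                          peak_sep_mm = 8, labels = NULL,
                          alternative = c("greater", "less", "two.sided"),
                          connectivity = 18L, p_map = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(stat, "stat_map"))
  if (p_voxel <= 0 || p_voxel >= 1) stop("p_voxel must be in (0, 1)", call. = FALSE)
  st <- supra_threshold(stat, p_voxel, alternative, p_map)
  supra <- st$supra
  score <- st$score
  empty <- tibble::tibble(
    cluster = integer(), size = integer(), label = integer(),
    laterality = character(), x = numeric(), y = numeric(), z = numeric(),
    t = numeric(), p = numeric()
  )
  if (!any(supra)) return(empty)
  lab <- label_components(supra, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > min_extent)
  if (length(keep) == 0L) return(empty)
  rows <- list()
  for (ci in seq_along(keep)) {
    k <- keep[ci]
    vox <- which(lab == k)
    co <- arrayInd(vox, dim(lab)) - 1L
    sc <- score[vox]
    ord <- order(sc, decreasing = TRUE)
    xyz <- voxel_to_world(stat$grid, co)
    peaks <- integer(0)
    for (i in ord) {
      if (length(peaks) == 3L) break
      if (length(peaks) == 0L ||
          all(sqrt(rowSums((xyz[peaks, , drop = FALSE] -
                            matrix(xyz[i, ], length(peaks), 3, byrow = TRUE))^2)) >=
              peak_sep_mm)) {
        peaks <- c(peaks, i)
      }
    }
    tv <- stat$t[vox[peaks]]
    pv <- switch(alternative,
      greater = stats::pt(tv, stat$df, lower.tail = FALSE),
      less = stats::pt(tv, stat$df),
      two.sided = 2 * stats::pt(abs(tv), stat$df, lower.tail = FALSE))
    lb <- if (!is.null(labels)) {
      as.integer(labels$values[vox[peaks]])
    } else {
      rep(NA_integer_, length(peaks))
    }
    rows[[ci]] <- tibble::tibble(
      cluster = ci, size = sizes[k], label = lb,
      laterality = ifelse(abs(xyz[peaks, 1]) < 1e-9, "M",
                          ifelse(xyz[peaks, 1] < 0, "L", "R")),
      x = xyz[peaks, 1], y = xyz[peaks, 2], z = xyz[peaks, 3],
      t = tv, p = pv, .peak_score = sc[peaks]
    )
  }
  out <- dplyr::bind_rows(rows)
  # renumber clusters by descending top-peak score; peaks stay score-sorted
  top <- vapply(split(out$.peak_score, out$cluster), max, numeric(1))
  rank_map <- rank(-top, ties.method = "first")
  out$cluster <- as.integer(rank_map[as.character(out$cluster)])
  out <- dplyr::arrange(out, .data$cluster, dplyr::desc(.data$.peak_score))
  out$.peak_score <- NULL
  out
}

#' Supra-threshold cluster membership mask
#'
#' Binary volume of all voxels belonging to clusters that survive the
#' voxel-forming and extent thresholds (same rules as [cluster_table()]).
#'
#' @inheritParams cluster_table
#' @return A [scalar_volume()] with values 0/1.
#' @export
cluster_mask <- function(stat, p_voxel = 0.001, min_extent = 100L,
                         alternative = c("greater", "less", "two.sided"),
                         connectivity = 18L, p_map = NULL) {
  alternative <- match.arg(alternative)
  supra <- supra_threshold(stat, p_voxel, alternative, p_map)$supra
  out <- array(0, dim = stat$grid$shape)
  if (any(supra)) {
    lab <- label_components(supra, connectivity)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes > min_extent)
    out[lab %in% keep] <- 1
  }
  scalar_volume(out, stat$grid)
}

#' Overlap of two cluster maps
#'
#' Voxelwise AND of two binary cluster-membership volumes on a shared grid,
#' with the overlapping voxel count.
#'
#' @param clusters_a,clusters_b Binary [scalar_volume()]s (e.g. from
#'   [cluster_mask()]).
#' @return A list: `mask` (binary [scalar_volume()]) and `n_voxels`.
#' @export
overlap_mask <- function(clusters_a, clusters_b) {
  stopifnot(inherits(clusters_a, "scalar_volume"),
            inherits(clusters_b, "scalar_volume"))
  if (!grids_equal(clusters_a$grid, clusters_b$grid)) {
    stop("cluster maps on mismatched grids", call. = FALSE)
  }
  both <- (clusters_a$values > 0) & (clusters_b$values > 0)
  list(mask = scalar_volume(both * 1, clusters_a$grid), n_voxels = sum(both))
}
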