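#' Volume sampling grid
#'
#' A `volume_grid` describes the sampling lattice shared by all volumes in an
#' analysis: the array shape in voxels, the voxel edge lengths in mm, and a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm
#' (RAS+ convention; a voxel's position is its center).
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#'   Ignored when `affine` is supplied (then derived from its column norms).
#' @param affine Optional 4x4 voxel-to-world matrix. Default places the grid
#'   center at the world origin with axes aligned to x/y/z.
#' @return An object of class `volume_grid` with fields `shape`, `voxel_size`
#'   and `affine`.
#' @examples
#' g <- volume_grid(c(40, 48, 40), voxel_size = c(2, 2, 2))
#' voxel_to_world(g, rbind(c(0, 0, 0)))
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
      stop("`voxel_size` must be 3 positive lengths (mm)", call. = FALSE)
    }
    affine <- diag(c(voxel_size, 1))
    # center the grid on the world origin
    affine[1:3, 4] <- -voxel_size * (shape - 1L) / 2
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) {
      stop("`affine` must be a 4x4 matrix", call. = FALSE)
    }
    det3 <- det(affine[1:3, 1:3])
    if (!is.finite(det3) || abs(det3) < .Machine$double.eps) {
      stop("`affine` must be invertible", call. = FALSE)
    }
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(
    "<volume_grid> ", paste(x$shape, collapse = " x "),
    " voxels @ ", paste(signif(x$voxel_size, 4), collapse = " x "), " mm\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname volume_grid
#' @param grid A `volume_grid`.
#' @param ijk Matrix of 0-based voxel indices, one row per voxel.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' @rdname volume_grid
#' @param xyz Matrix of world coordinates in mm, one row per point.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ijk1 <- cbind(xyz, 1) %*% t(solve(grid$affine))
  ijk1[, 1:3, drop = FALSE]
}

voxel_volume <- function(grid) prod(grid$voxel_size)

grids_equal <- function(a, b, tol = 1e-8) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Scalar volume on a grid
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid A [volume_grid()].
#' @return A `scalar_volume`: the array with the grid attached.
#' @export
scalar_volume <- function(values, grid) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape)) {
    stop("`values` must be a 3D array matching grid shape", call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume>\n")
  print(x$grid)
  rng <- range(x$values, na.rm = TRUE)
  cat("  values in [", signif(rng[1], 4), ", ", signif(rng[2], 4), "]\n", sep = "")
  invisible(x)
}
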