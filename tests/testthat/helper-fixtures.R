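# Shared fixtures: everything generated in code, nothing on disk.

small_grid <- function(shape = c(20L, 24L, 20L), vs = c(2, 2, 2)) {
  volume_grid(shape, vs)
}

# Independent brute-force oracle for sphere voxel counts: enumerate integer
# voxel offsets around a center placed on a voxel center.
brute_force_sphere_count <- function(radius_mm, voxel_mm) {
  r <- ceiling(radius_mm / voxel_mm) + 1L
  count <- 0L
  for (i in -r:r) for (j in -r:r) for (k in -r:r) {
    if ((i * voxel_mm)^2 + (j * voxel_mm)^2 + (k * voxel_mm)^2 <= radius_mm^2) {
      count <- count + 1L
    }
  }
  count
}

# Random symmetric positive-definite tensor within physiological scale.
random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3)
  D <- crossprod(A)
  D <- D / max(eigen(D, only.values = TRUE)$values) * 2e-3 + diag(3) * 2e-4
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

uniform_tensor_volume <- function(d6, grid = small_grid(c(3L, 3L, 3L))) {
  vals <- array(0, dim = c(grid$shape, 6L))
  for (k in 1:6) vals[, , , k] <- d6[k]
  glymphalps:::tensor_volume(vals, grid)
}

# A stat_map with prescribed T values, for cluster fixtures.
fake_stat_map <- function(tvals, grid, df = 100) {
  structure(
    list(t = tvals, df = df, mask = array(TRUE, dim = grid$shape),
         grid = grid, contrast = c(0, 1), n = df + 2, n_degenerate = 0L),
    class = "stat_map"
  )
}

null_synth_params <- function(n_yoad = 25L, n_ctl = 25L, seed = 1L, ...) {
  synth_params(
    n_yoad = n_yoad, n_ctl = n_ctl,
    alps_shift_yoad = 0, gm_coupling = 0,
    mediation = list(a = 0, b = 0, c_prime = 0, sd_m = 12, sd_y = 8, m0 = 700),
    seed = seed, ...
  )
}
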