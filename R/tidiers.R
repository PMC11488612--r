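#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mediation fit
#'
#' One row per path (`a`, `b`, `c_prime`, `c`) plus an `indirect` row
#' carrying the bootstrap CI.
#'
#' @param x A `mediation_fit` from [mediate()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `ci_lower`, `ci_upper`.
#' @export
tidy.mediation_fit <- function(x, ...) {
  paths <- tibble::tibble(
    term = x$paths$path, estimate = x$paths$estimate,
    std_error = x$paths$std_error, statistic = x$paths$statistic,
    p_value = x$paths$p_value, ci_lower = NA_real_, ci_upper = NA_real_
  )
  dplyr::bind_rows(paths, tibble::tibble(
    term = "indirect", estimate = x$indirect, std_error = stats::sd(x$boot),
    statistic = NA_real_, p_value = NA_real_,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper
  ))
}

#' @rdname tidy.mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, indirect = x$indirect, ci_lower = x$ci_lower,
    ci_upper = x$ci_upper, z0 = x$z0, B = x$B, alpha = x$alpha,
    classification = x$classification, n_redrawn = x$n_redrawn
  )
}

#' Tidy a voxelwise stat map into its cluster table
#'
#' @param x A `stat_map` from [voxelwise_glm()].
#' @param ... Passed to [cluster_table()] (`p_voxel`, `min_extent`, ...).
#' @return The [cluster_table()] tibble.
#' @export
tidy.stat_map <- function(x, ...) {
  cluster_table(x, ...)
}

#' @rdname tidy.stat_map
#' @export
glance.stat_map <- function(x, ...) {
  tibble::tibble(
    n = x$n, df = x$df, n_voxels = sum(x$mask),
    max_t = max(x$t, na.rm = TRUE), min_t = min(x$t, na.rm = TRUE),
    n_degenerate = x$n_degenerate
  )
}
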