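#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ALPS distributions by group
#'
#' Jittered points with group mean +/- SD overlay, mirroring the usual
#' group-distribution figure for the ALPS index.
#'
#' @param data Cohort tibble containing the ALPS column and `group`.
#' @param alps Column name to plot (default `"alps_bilateral"`).
#' @return A ggplot object.
#' @export
plot_alps_groups <- function(data, alps = "alps_bilateral") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data[[alps]],
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", colour = "black") +
    ggplot2::labs(x = NULL, y = "ALPS index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Axial slice of a stat map
#'
#' @param object A `stat_map`.
#' @param z_mm World z coordinate of the displayed axial slice (defaults to
#'   the slice holding the largest |T|).
#' @param ... Unused.
#' @return A ggplot object (tile heatmap of T, masked voxels blank).
#' @export
autoplot.stat_map <- function(object, z_mm = NULL, ...) {
  tz <- object$t
  if (is.null(z_mm)) {
    k <- which.max(apply(abs(tz), 3, max, na.rm = TRUE))
  } else {
    zs <- voxel_to_world(object$grid,
                         cbind(0, 0, seq_len(object$grid$shape[3]) - 1L))[, 3]
    k <- which.min(abs(zs - z_mm))
  }
  sl <- tz[, , k]
  df <- expand.grid(i = seq_len(nrow(sl)) - 1L, j = seq_len(ncol(sl)) - 1L)
  xy <- voxel_to_world(object$grid, cbind(df$i, df$j, k - 1L))
  df$x <- xy[, 1]; df$y <- xy[, 2]
  df$t <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90", high = "red",
                                  na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "T") +
    ggplot2::theme_minimal()
}

#' Bootstrap distribution of the indirect effect
#'
#' @param object A `mediation_fit`.
#' @param ... Unused.
#' @return A ggplot histogram with the point estimate and BC CI marked.
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- tibble::tibble(ab = object$boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ab)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$indirect, colour = "black") +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "bootstrap a*b", y = "count") +
    ggplot2::theme_minimal()
}
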