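# ggplot2 views of trajectories, evaluations and activation clusters.

#' Plot a soaring trajectory
#'
#' Ground track in the xy plane coloured by climb rate, with the drifting
#' thermal center shown as a dashed line.
#'
#' @param traj Trajectory tibble.
#' @param center Draw the drifting thermal-center path. Default TRUE.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, center = TRUE) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$vz), linewidth = 0.6) +
    ggplot2::scale_colour_viridis_c(name = expression(v[z] ~ "(m/s)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
  if (center && all(c("u", "t") %in% names(traj))) {
    ctr <- tibble::tibble(x = traj$u * traj$t, y = 0)
    p <- p + ggplot2::geom_path(data = ctr, linetype = "dashed",
                                colour = "grey40")
  }
  p
}

#' @export
autoplot.soaring_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$u), .data$eta)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "horizontal wind u (m/s)",
                  y = expression(eta ~ "(soaring efficiency)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.activation_clusters <- function(object, ...) {
  knee <- object$k
  ggplot2::ggplot(object$sse, ggplot2::aes(.data$k, .data$sse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = knee, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "number of clusters k", y = "within-cluster SSE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soaring_summary <- function(object, ...) {
  ggplot2::ggplot(object$position_hist,
                  ggplot2::aes(.data$x_bin, .data$y_bin, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x - x_center (m)", y = "y (m)", fill = "samples") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster theta distributions
#'
#' @param dist Output of [cluster_theta_distribution()].
#' @return A ggplot object.
#' @export
plot_theta_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(.data$theta_bin, .data$prop,
                                     fill = factor(.data$cluster))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = expression(theta ~ "(deg)"), y = "fraction of cluster",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}
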