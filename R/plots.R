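#' Top view of a trajectory set
#'
#' Ground-track (x-z plane) paths of each trajectory as seen from above,
#' with the observer at the origin. Mirrored variants are drawn with their
#' signed lateral offset.
#'
#' @param spec A trajectory tibble.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(spec) {
  validate_trajectories(spec)
  paths <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    row <- spec[i, ]
    st <- ball_state(row, seq(0, row$flight_time, length.out = 101))
    tibble::tibble(traj_id = row$traj_id, gs_rel = row$gs_rel,
                   x = st$x, z = st$z)
  })
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$x, y = .data$z,
                                      group = .data$traj_id,
                                      colour = factor(.data$gs_rel))) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 0, y = 0, shape = 17, size = 3) +
    ggplot2::labs(x = "lateral position x (m)", y = "depth z (m)",
                  colour = "design fraction") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a GS prediction-error profile
#'
#' Prediction error against time elapsed since launch, one line per
#' trajectory, with the zero-error level dashed. Positive errors are
#' overestimates of the remaining TTC.
#'
#' @param object A `gs_profile` tibble from [gs_error_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gs_profile
#' @export
autoplot.gs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$error,
                                       colour = factor(.data$gs_rel),
                                       group = .data$traj_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since launch (s)",
                  y = "TTC prediction error (s)",
                  colour = "design fraction") +
    ggplot2::theme_minimal()
}

#' Plot per-participant performance
#'
#' Hit probability against response-time variability per participant and
#' flight duration, coloured by viewer class.
#'
#' @param metrics Result of [performance_metrics()].
#' @return A ggplot object.
#' @export
plot_performance <- function(metrics) {
  ggplot2::ggplot(metrics$by_duration,
                  ggplot2::aes(x = .data$rt_sd, y = .data$hit_prob,
                               colour = .data$viewer_class,
                               shape = factor(.data$flight_time))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "response-time SD (s)", y = "hit probability",
                  colour = "viewer class", shape = "flight time (s)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
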