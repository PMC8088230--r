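#' Project ball kinematics into monocular optic variables
#'
#' Maps Cartesian ball states to the optic variables seen from the eye:
#' angular (retinal) size `theta = 2*atan(r/d)`, elevation angle
#' `gamma = atan(y / rho)` (rho the horizontal distance), its analytic
#' rate of change `gamma_dot = (vy*rho - y*rho_dot) / d^2`, and the
#' azimuth `beta = atan2(|x|, z)` measured from the initial line of sight,
#' so `beta > pi/2` exactly when the ball is behind the observer's frontal
#' plane. All angles are radians.
#'
#' @param states A tibble of kinematic states as from [ball_state()]
#'   (columns `t`, `x`, `y`, `z`, `vx`, `vy`, `vz`).
#' @param ball_radius Ball radius in metres.
#' @return A tibble with columns `t`, `theta`, `gamma`, `gamma_dot`
#'   (rad, rad, rad/s), `beta` (rad in [0, pi]) and `d` (metres).
#' @examples
#' spec <- trajectory(25.16, 10.06, -5.03, 3)
#' project_optics(ball_state(spec, c(0, 1.5)), spec$ball_radius)
#' @export
project_optics <- function(states, ball_radius) {
  d <- sqrt(states$x^2 + states$y^2 + states$z^2)
  if (any(d <= ball_radius)) {
    abort("eye lies inside the ball (d <= ball_radius)",
          class = "parattc_inside_ball_error")
  }
  rho <- sqrt(states$x^2 + states$z^2)
  if (any(rho == 0)) {
    abort("ball directly above/below the eye; elevation angle undefined",
          class = "parattc_degenerate_error")
  }
  rho_dot <- (states$x * states$vx + states$z * states$vz) / rho
  tibble::tibble(
    t = states$t,
    theta = 2 * atan(ball_radius / d),
    gamma = atan(states$y / rho),
    gamma_dot = (states$vy * rho - states$y * rho_dot) / d^2,
    beta = atan2(abs(states$x), states$z),
    d = d
  )
}

#' Optic-variable time series over a flight
#'
#' Samples a trajectory at `t = 0, dt, ..., T` (the endpoint is always
#' included) and projects every state into optic variables. Samples with
#' the eye inside the ball are dropped.
#'
#' @param spec A one-row trajectory tibble.
#' @param dt Time step in seconds, `0 < dt <= flight_time`.
#' @return An optic-state tibble, strictly increasing in `t`.
#' @export
optic_series <- function(spec, dt) {
  stopifnot(nrow(spec) == 1)
  if (dt <= 0 || dt > spec$flight_time) {
    abort("dt must satisfy 0 < dt <= flight_time",
          class = "parattc_range_error")
  }
  t <- seq(0, spec$flight_time, by = dt)
  if (spec$flight_time - t[length(t)] > 1e-9) {
    t <- c(t, spec$flight_time)
  }
  states <- ball_state(spec, t)
  d <- sqrt(states$x^2 + states$y^2 + states$z^2)
  project_optics(states[d > spec$ball_radius, ], spec$ball_radius)
}
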