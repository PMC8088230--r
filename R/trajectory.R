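#' Build a table of parabolic trajectory specifications
#'
#' A trajectory is a gravity-only parabolic flight launched and landing at
#' the observer's eye level (the plane y = 0). The observer's eye is the
#' origin of a right-handed frame with y up and +z pointing toward the
#' launch point; the ball is launched from (0, 0, `z_init`) and lands at
#' (+/- `x_end`, 0, `z_end`). `x_end` is stored as a magnitude; `side`
#' records whether the lateral offset is to the observer's left or right.
#' A negative `z_end` places the landing point behind the observer.
#'
#' @param z_init Depth of the launch point in metres (> 0).
#' @param x_end Magnitude of the lateral landing offset in metres (>= 0).
#' @param z_end Depth of the landing point in metres; may be negative.
#' @param flight_time Total flight duration T in seconds (> 0).
#' @param g Gravitational acceleration in m/s^2 (default standard gravity).
#' @param ball_radius Ball radius in metres (default 0.11, a soccer ball).
#' @param side `"left"` or `"right"`; lateral sign of the landing point.
#' @param gs_rel Design fraction of flight time in (0, 1) at which the GS
#'   model error is zero. A label carried with the spec; use
#'   [privileged_time()] to compute the realised value.
#' @param traj_id Optional identifier; autogenerated when `NULL`.
#'
#' @return A tibble with one row per trajectory and columns `traj_id`,
#'   `gs_rel`, `z_init`, `x_end`, `z_end`, `flight_time`, `g`,
#'   `ball_radius`, `side`.
#'
#' @examples
#' trajectory(z_init = 25.16, x_end = 10.06, z_end = -5.03, flight_time = 3)
#' @export
trajectory <- function(z_init, x_end, z_end, flight_time,
                       g = 9.807, ball_radius = 0.11,
                       side = "right", gs_rel = NA_real_, traj_id = NULL) {
  n <- max(length(z_init), length(x_end), length(z_end), length(flight_time))
  spec <- tibble::tibble(
    traj_id = if (is.null(traj_id)) {
      sprintf("traj%02d", seq_len(n))
    } else {
      as.character(traj_id)
    },
    gs_rel = as.numeric(gs_rel),
    z_init = as.numeric(z_init),
    x_end = as.numeric(x_end),
    z_end = as.numeric(z_end),
    flight_time = as.numeric(flight_time),
    g = as.numeric(g),
    ball_radius = as.numeric(ball_radius),
    side = as.character(side)
  )
  validate_trajectories(spec)
}

#' Validate a trajectory table
#'
#' Checks the invariants every downstream computation relies on: positive
#' flight time, gravity, ball radius and launch depth, a non-negative
#' lateral offset magnitude, and a `side` of `"left"` or `"right"`.
#'
#' @param spec A trajectory tibble as returned by [trajectory()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_trajectories <- function(spec) {
  required <- c(
    "traj_id", "gs_rel", "z_init", "x_end", "z_end",
    "flight_time", "g", "ball_radius", "side"
  )
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0) {
    abort(paste0(
      "trajectory table is missing column(s): ",
      paste(missing, collapse = ", ")
    ), class = "parattc_format_error")
  }
  bad <- function(cond, msg) {
    if (any(cond)) abort(msg, class = "parattc_validation_error")
  }
  bad(!is.finite(spec$flight_time) | spec$flight_time <= 0,
      "flight_time must be > 0")
  bad(!is.finite(spec$z_init) | spec$z_init <= 0, "z_init must be > 0")
  bad(!is.finite(spec$g) | spec$g <= 0, "g must be > 0")
  bad(!is.finite(spec$ball_radius) | spec$ball_radius <= 0,
      "ball_radius must be > 0")
  bad(!is.finite(spec$x_end) | spec$x_end < 0,
      "x_end is a magnitude and must be >= 0")
  bad(!spec$side %in% c("left", "right"),
      "side must be 'left' or 'right'")
  spec
}

#' Launch velocity of a parabolic flight
#'
#' With launch and landing both at eye level the vertical launch speed is
#' fixed at g*T/2 (so the height returns to zero exactly at t = T), and the
#' horizontal components are constants fixed by the endpoints:
#' vx = +/- x_end / T (sign per `side`), vz = (z_end - z_init) / T.
#'
#' @param spec A trajectory tibble (any number of rows).
#' @return A tibble with columns `traj_id`, `vx`, `vy0`, `vz` in m/s.
#' @examples
#' launch_velocity(trajectory(25.16, 10.06, -5.03, 3))
#' @export
launch_velocity <- function(spec) {
  validate_trajectories(spec)
  tibble::tibble(
    traj_id = spec$traj_id,
    vx = ifelse(spec$side == "left", -1, 1) * spec$x_end / spec$flight_time,
    vy0 = spec$g * spec$flight_time / 2,
    vz = (spec$z_end - spec$z_init) / spec$flight_time
  )
}

#' Ball kinematic state at given times
#'
#' Closed-form projectile kinematics of one trajectory: constant horizontal
#' velocity, uniform vertical deceleration under gravity.
#'
#' @param spec A one-row trajectory tibble.
#' @param t Vector of times since launch, seconds; each must lie in [0, T].
#' @return A tibble with columns `t`, `x`, `y`, `z` (metres) and `vx`,
#'   `vy`, `vz` (m/s) in the observer-centred frame.
#' @export
ball_state <- function(spec, t) {
  stopifnot(nrow(spec) == 1)
  validate_trajectories(spec)
  if (any(t < 0 | t > spec$flight_time)) {
    abort("t must lie within [0, flight_time]",
          class = "parattc_range_error")
  }
  v <- launch_velocity(spec)
  tibble::tibble(
    t = t,
    x = v$vx * t,
    y = v$vy0 * t - spec$g * t^2 / 2,
    z = spec$z_init + v$vz * t,
    vx = rep(v$vx, length(t)),
    vy = v$vy0 - spec$g * t,
    vz = rep(v$vz, length(t))
  )
}

#' Horizontal ground-track distance as a function of flight fraction
#'
#' The horizontal (eye-level plane) distance rho(tau) between observer and
#' ball at flight fraction tau = t/T, together with its derivative with
#' respect to tau. The ratio rho'/rho drives the GS model's prediction
#' error, so this is the quantity the zero-error condition is written in.
#'
#' @param spec A one-row trajectory tibble.
#' @param tau Vector of flight fractions in [0, 1].
#' @return A tibble with columns `tau`, `rho` (m), `drho_dtau` (m per unit
#'   fraction).
#' @export
ground_track <- function(spec, tau) {
  stopifnot(nrow(spec) == 1)
  validate_trajectories(spec)
  if (any(tau < 0 | tau > 1)) {
    abort("tau must lie within [0, 1]", class = "parattc_range_error")
  }
  x <- spec$x_end * tau
  z <- spec$z_init + (spec$z_end - spec$z_init) * tau
  rho <- sqrt(x^2 + z^2)
  if (any(rho == 0)) {
    abort("ball passes exactly through the eye; ground track degenerate",
          class = "parattc_degenerate_error")
  }
  tibble::tibble(
    tau = tau,
    rho = rho,
    drho_dtau = (x * spec$x_end + z * (spec$z_end - spec$z_init)) / rho
  )
}

#' The tailored ten-trajectory experimental set
#'
#' Five endpoint triples, each tailored so the GS model's prediction error
#' crosses zero at 30, 40, 50, 60 or 70% of flight time, crossed with two
#' flight durations (3 and 3.5 s). With `mirrored = TRUE` each spec is
#' duplicated with the lateral offset to the left and to the right
#' (20 labelled variants).
#'
#' @param mirrored Include left/right mirror variants (default `FALSE`).
#' @return A trajectory tibble with 10 (or 20) rows.
#' @examples
#' experiment_trajectories()
#' @export
experiment_trajectories <- function(mirrored = FALSE) {
  z_init <- c(23.49, 24.23, 25.16, 26.24, 27.47)
  x_end <- c(15.09, 12.53, 10.06, 7.71, 5.53)
  z_end <- c(-4.53, -5.01, -5.03, -4.63, -3.87)
  gs_rel <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  grid <- tidyr::expand_grid(
    i = 1:5,
    flight_time = c(3, 3.5),
    side = if (mirrored) c("left", "right") else "right"
  )
  trajectory(
    z_init = z_init[grid$i],
    x_end = x_end[grid$i],
    z_end = z_end[grid$i],
    flight_time = grid$flight_time,
    side = grid$side,
    gs_rel = gs_rel[grid$i],
    traj_id = sprintf(
      "gs%02.0f_T%.1f%s", 100 * gs_rel[grid$i], grid$flight_time,
      if (mirrored) paste0("_", substr(grid$side, 1, 1)) else ""
    )
  )
}

trajectory_csv_map <- c(
  traj_id = "traj_id", gs_rel = "gs_rel", z_init = "z_init_m",
  x_end = "x_end_m", z_end = "z_end_m", flight_time = "flight_time_s",
  g = "g_ms2", ball_radius = "ball_radius_m", side = "side"
)

#' Read / write trajectory tables
#'
#' CSV interchange with unit-suffixed headers (`z_init_m`,
#' `flight_time_s`, ...). Reading validates the header and the usual
#' trajectory invariants.
#'
#' @param spec A trajectory tibble.
#' @param path File path.
#' @return `read_trajectories()` returns a trajectory tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(spec, path) {
  validate_trajectories(spec)
  out <- spec[names(trajectory_csv_map)]
  names(out) <- unname(trajectory_csv_map)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(unname(trajectory_csv_map), names(raw))
  if (length(missing) > 0) {
    abort(paste0("trajectory CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "parattc_format_error")
  }
  out <- raw[unname(trajectory_csv_map)]
  names(out) <- names(trajectory_csv_map)
  validate_trajectories(tibble::as_tibble(out))
}
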