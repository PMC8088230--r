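#' GS-model predicted time to contact
#'
#' The gravity-and-size (GS) heuristic combines prior knowledge of the
#' ball's physical size s = 2r and of gravitational acceleration g with
#' three monocular optic variables -- angular size theta, elevation angle
#' gamma and its rate of change gamma_dot -- into a prediction of the time
#' remaining until the ball returns to eye level:
#'
#'   TTC_GS = (2 / g) * (s / theta) * gamma_dot / cos(gamma)
#'
#' s/theta recovers distance from angular size; g normalises the elevation
#' rate into seconds. The prediction is exact throughout head-on flights
#' (landing on the eye) and exact at launch for every flight; for lateral
#' trajectories it first overestimates, is exactly right at one
#' privileged moment, then underestimates.
#'
#' @param optics An optic-state tibble (columns `theta`, `gamma`,
#'   `gamma_dot`), as from [project_optics()].
#' @param ball_diameter Physical ball diameter s in metres.
#' @param g Gravitational acceleration, m/s^2.
#' @return Numeric vector of predicted remaining TTC in seconds (one per
#'   row of `optics`); the sign follows `gamma_dot`.
#' @examples
#' spec <- trajectory(25.16, 10.06, -5.03, 3)
#' opt <- project_optics(ball_state(spec, 0.001), spec$ball_radius)
#' gs_ttc(opt, 2 * spec$ball_radius, spec$g) # ~ 3 s at launch
#' @export
gs_ttc <- function(optics, ball_diameter, g) {
  if (any(optics$theta <= 0)) {
    abort("theta must be > 0", class = "parattc_validation_error")
  }
  if (any(abs(cos(optics$gamma)) < 1e-12)) {
    abort("cos(gamma) = 0; GS prediction undefined",
          class = "parattc_undefined_error")
  }
  (2 / g) * (ball_diameter / optics$theta) *
    optics$gamma_dot / cos(optics$gamma)
}

# Vectorised GS prediction at arbitrary times for rows carrying their own
# trajectory parameters. Closed form; no per-row tibble construction so it
# stays cheap inside the trial generator and the correspondence analysis.
gs_ttc_points <- function(z_init, x_end, z_end, flight_time, g,
                          ball_radius, t) {
  vx <- x_end / flight_time
  vy0 <- g * flight_time / 2
  vz <- (z_end - z_init) / flight_time
  x <- vx * t
  y <- vy0 * t - g * t^2 / 2
  z <- z_init + vz * t
  d <- sqrt(x^2 + y^2 + z^2)
  rho <- sqrt(x^2 + z^2)
  rho_dot <- (x * vx + z * vz) / rho
  gamma <- atan(y / rho)
  gamma_dot <- ((vy0 - g * t) * rho - y * rho_dot) / d^2
  theta <- 2 * atan(ball_radius / d)
  (2 / g) * (2 * ball_radius / theta) * gamma_dot / cos(gamma)
}

# GS prediction error (predicted minus true remaining time) at time t for
# a one-row spec; scalar-friendly, used by the root finders.
gs_error_at <- function(spec, t) {
  gs_ttc_points(spec$z_init, spec$x_end, spec$z_end, spec$flight_time,
                spec$g, spec$ball_radius, t) -
    (spec$flight_time - t)
}

#' GS prediction-error profile over a flight
#'
#' Evaluates the GS predictor through the full optic projection on a
#' regular time grid and returns, per trajectory, the predicted remaining
#' TTC, the true remaining time `T - t`, and their difference. Positive
#' errors are overestimates of the remaining time. The grid stops 1 ms
#' before landing to avoid the vanishing-distance regime.
#'
#' @param spec A trajectory tibble (any number of rows).
#' @param dt Grid step in seconds (default 1 ms).
#' @return A tibble of class `gs_profile` with columns `traj_id`, `gs_rel`,
#'   `t`, `ttc_gs`, `ttc_true`, `error` (seconds).
#' @examples
#' prof <- gs_error_profile(trajectory(25.16, 10.06, -5.03, 3), dt = 0.01)
#' @export
gs_error_profile <- function(spec, dt = 0.001) {
  validate_trajectories(spec)
  if (dt <= 0) abort("dt must be > 0", class = "parattc_range_error")
  out <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    row <- spec[i, ]
    t <- seq(0, row$flight_time - 0.001, by = dt)
    opt <- project_optics(ball_state(row, t), row$ball_radius)
    tibble::tibble(
      traj_id = row$traj_id,
      gs_rel = row$gs_rel,
      t = opt$t,
      ttc_gs = gs_ttc(opt, 2 * row$ball_radius, row$g),
      ttc_true = row$flight_time - opt$t
    )
  })
  out$error <- out$ttc_gs - out$ttc_true
  class(out) <- c("gs_profile", class(out))
  out
}

#' Privileged zero-error time of a trajectory
#'
#' The moment within a lateral flight at which the GS prediction error
#' crosses zero (prediction exactly equal to the true remaining time).
#' The error profile also touches zero at launch; the privileged point is
#' the first positive-to-negative crossing after 5% of flight time. The
#' crossing is bracketed on a 1 ms grid and refined by bisection to 1e-6 s.
#'
#' @param spec A trajectory tibble; one value is returned per row.
#' @param dt Scan-grid step in seconds (default 1 ms).
#' @return Numeric vector of zero-crossing times in seconds.
#' @examples
#' privileged_time(trajectory(25.16, 10.06, -5.03, 3, gs_rel = 0.5)) # 1.5 s
#' @export
privileged_time <- function(spec, dt = 0.001) {
  validate_trajectories(spec)
  purrr::map_dbl(seq_len(nrow(spec)), function(i) {
    row <- spec[i, ]
    t <- seq(0.05 * row$flight_time, row$flight_time - 0.001, by = dt)
    err <- gs_error_at(row, t)
    cross <- which(err[-length(err)] > 0 & err[-1] <= 0)
    if (length(cross) == 0) {
      abort(paste0("no zero crossing of the GS error found for ",
                   row$traj_id),
            class = "parattc_no_privileged_time_error")
    }
    j <- cross[1]
    uniroot(function(tt) gs_error_at(row, tt),
            lower = t[j], upper = t[j + 1], tol = 1e-6)$root
  })
}

#' Weber-fraction discriminability of optic cues between flight durations
#'
#' Compares the optic cues available at the last visible frame of a short
#' and a long flight, plus the GS-model output as a composite cue, and
#' asks whether the relative difference exceeds a Weber fraction. The
#' relative difference is the proportion of change from the short-flight
#' value, `|c_long - c_short| / |c_short| * 100`.
#'
#' @param spec_short,spec_long One-row trajectory tibbles for the two
#'   flight durations.
#' @param t_last_visible Length-2 vector: last visible time in the short
#'   and long flights respectively, seconds.
#' @param weber Weber fraction threshold (default 0.05, i.e. 5%).
#' @return A tibble with columns `cue` (`theta`, `gamma`, `gamma_dot`,
#'   `gs_output`), `value_short`, `value_long`, `rel_diff_pct`,
#'   `discriminable`.
#' @export
cue_discriminability <- function(spec_short, spec_long, t_last_visible,
                                 weber = 0.05) {
  stopifnot(nrow(spec_short) == 1, nrow(spec_long) == 1,
            length(t_last_visible) == 2)
  if (t_last_visible[1] < 0 || t_last_visible[1] > spec_short$flight_time ||
      t_last_visible[2] < 0 || t_last_visible[2] > spec_long$flight_time) {
    abort("t_last_visible must lie within each flight",
          class = "parattc_range_error")
  }
  value_at <- function(spec, t) {
    opt <- project_optics(ball_state(spec, t), spec$ball_radius)
    c(
      theta = opt$theta,
      gamma = opt$gamma,
      gamma_dot = opt$gamma_dot,
      gs_output = gs_ttc(opt, 2 * spec$ball_radius, spec$g)
    )
  }
  cs <- value_at(spec_short, t_last_visible[1])
  cl <- value_at(spec_long, t_last_visible[2])
  if (any(cs == 0 & cl == 0)) {
    abort(paste0("cue(s) zero in both flights; relative difference ",
                 "undefined: ",
                 paste(names(cs)[cs == 0 & cl == 0], collapse = ", ")),
          class = "parattc_undefined_ratio_error")
  }
  if (any(cs == 0)) {
    abort("short-flight cue value is zero; relative difference undefined",
          class = "parattc_undefined_ratio_error")
  }
  rel <- abs(cl - cs) / abs(cs) * 100
  tibble::tibble(
    cue = names(cs),
    value_short = unname(cs),
    value_long = unname(cl),
    rel_diff_pct = unname(rel),
    discriminable = unname(rel) >= weber * 100
  )
}
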