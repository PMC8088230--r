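# Zero-error condition in the flight-fraction domain. Writing the GS error
# with phi(tau) = tau - tau^2 (scaled height) gives
#   error(tau) = -T * tau * (1 + (1 - tau) * rho'(tau) / rho(tau))
# so the error vanishes (for tau > 0) exactly where
#   rho'(tau) / rho(tau) = -1 / (1 - tau).
# The condition involves only the ground track, hence is independent of T:
# the same endpoint triple yields the same privileged *fraction* for every
# flight duration.
zero_error_condition <- function(z_init, x_end, z_end, tau) {
  x <- x_end * tau
  z <- z_init + (z_end - z_init) * tau
  rho2 <- x^2 + z^2
  drho_rho <- (x * x_end + z * (z_end - z_init)) / rho2
  drho_rho + 1 / (1 - tau)
}

#' Design a trajectory with zero GS error at a prescribed flight fraction
#'
#' Inverse problem: given a target fraction f in (0, 1) and two of the
#' three endpoint parameters (`z_init`, `x_end`, `z_end`), solve for the
#' third so that the GS model's prediction error crosses zero exactly at
#' t = f * T. The scalar zero-error condition
#' `rho'(tau)/rho(tau) = -1/(1 - tau)` is solved in the free parameter by
#' bracketed bisection; the result is then verified through the full optic
#' projection via [privileged_time()].
#'
#' @param target_fraction Desired zero-error fraction of flight time,
#'   in (0, 1).
#' @param flight_time Flight duration T in seconds.
#' @param fixed Named numeric vector fixing exactly two of `z_init`,
#'   `x_end`, `z_end` (metres).
#' @param free Name of the remaining free parameter; defaults to the one
#'   not in `fixed`.
#' @param interval Search interval for the free parameter, metres.
#' @param g,ball_radius,side Passed to [trajectory()].
#' @param tol Root tolerance on the free parameter, metres.
#' @return A one-row trajectory tibble whose `gs_rel` is `target_fraction`.
#'   If the condition has several roots in `interval`, the smallest free
#'   parameter is returned with a warning.
#' @examples
#' design_trajectory(0.5, 3, fixed = c(x_end = 10.06, z_end = -5.03))
#' @export
design_trajectory <- function(target_fraction, flight_time,
                              fixed, free = NULL,
                              interval = c(1, 60),
                              g = 9.807, ball_radius = 0.11,
                              side = "right", tol = 1e-10) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    abort("target_fraction must lie in (0, 1)",
          class = "parattc_validation_error")
  }
  pars <- c("z_init", "x_end", "z_end")
  if (length(fixed) != 2 || !all(names(fixed) %in% pars)) {
    abort("fixed must name exactly two of z_init, x_end, z_end",
          class = "parattc_validation_error")
  }
  if (is.null(free)) free <- setdiff(pars, names(fixed))
  if (length(free) != 1 || free %in% names(fixed)) {
    abort("exactly one parameter must be free",
          class = "parattc_validation_error")
  }
  cond <- function(p) {
    full <- c(fixed, setNames(p, free))
    zero_error_condition(full[["z_init"]], full[["x_end"]],
                         full[["z_end"]], target_fraction)
  }
  grid <- seq(interval[1], interval[2], length.out = 512)
  vals <- vapply(grid, cond, numeric(1))
  if (all(abs(vals) < 1e-9, na.rm = TRUE)) {
    # degenerate geometry (e.g. head-on): the condition holds identically
    # and the error never crosses zero, so no fraction can be prescribed
    abort("design infeasible: the GS error has no zero crossing to place",
          class = "parattc_design_infeasible_error")
  }
  sign_change <- which(vals[-length(vals)] * vals[-1] < 0 &
                         is.finite(vals[-length(vals)]) &
                         is.finite(vals[-1]))
  if (length(sign_change) == 0) {
    abort(paste0("design infeasible: the zero-error condition does not ",
                 "change sign over the search interval"),
          class = "parattc_design_infeasible_error")
  }
  if (length(sign_change) > 1) {
    warn(paste0("multiple roots in the search interval; ",
                "returning the smallest free-parameter value"))
  }
  j <- sign_change[1]
  root <- uniroot(cond, lower = grid[j], upper = grid[j + 1],
                  tol = tol)$root
  full <- c(fixed, setNames(root, free))
  spec <- trajectory(
    z_init = full[["z_init"]], x_end = full[["x_end"]],
    z_end = full[["z_end"]], flight_time = flight_time,
    g = g, ball_radius = ball_radius, side = side,
    gs_rel = target_fraction,
    traj_id = sprintf("design_gs%02.0f_T%.1f", 100 * target_fraction,
                      flight_time)
  )
  realised <- tryCatch(
    privileged_time(spec) / flight_time,
    error = function(e) {
      abort("design infeasible: the GS error has no zero crossing to place",
            class = "parattc_design_infeasible_error")
    }
  )
  if (abs(realised - target_fraction) >= 1e-4) {
    abort(sprintf(
      "designed trajectory fails verification: realised fraction %.6f vs target %.6f",
      realised, target_fraction
    ), class = "parattc_design_infeasible_error")
  }
  spec
}
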