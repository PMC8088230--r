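# Independent oracles, written directly from the flight geometry and kept
# free of the package's optic-projection code path.

# Remaining-TTC prediction of the gravity-and-size heuristic in the
# flight-fraction domain: with phi(tau) = tau - tau^2 (height scaled by
# g*T^2/2) the predictor reduces to
#   ttc(tau) = T * (phi'(tau) - phi(tau) * rho'(tau) / rho(tau))
# where rho is the horizontal eye-ball distance. Uses only endpoint
# algebra, no angular projection.
oracle_gs_ttc <- function(z_init, x_end, z_end, flight_time, t) {
  tau <- t / flight_time
  x <- x_end * tau
  z <- z_init + (z_end - z_init) * tau
  rho <- sqrt(x^2 + z^2)
  drho <- (x * x_end + z * (z_end - z_init)) / rho # d rho / d tau
  phi <- tau - tau^2
  dphi <- 1 - 2 * tau
  flight_time * (dphi - phi * drho / rho)
}

# Zero-error fraction: solves rho'(tau)/rho(tau) = -1/(1-tau) by dense
# grid scan plus bisection, independently of the package root finder.
oracle_privileged_fraction <- function(z_init, x_end, z_end) {
  f <- function(tau) {
    x <- x_end * tau
    z <- z_init + (z_end - z_init) * tau
    rho2 <- x^2 + z^2
    (x * x_end + z * (z_end - z_init)) / rho2 + 1 / (1 - tau)
  }
  taus <- seq(0.02, 0.98, by = 1e-4)
  vals <- vapply(taus, f, numeric(1))
  j <- which(vals[-length(vals)] * vals[-1] <= 0)[1]
  stopifnot(!is.na(j))
  uniroot(f, c(taus[j], taus[j + 1]), tol = 1e-10)$root
}

# The endpoint triple printed for the mid-fraction (50%) trajectory; used
# across test files.
mid_spec <- function(flight_time = 3, ...) {
  trajectory(z_init = 25.16, x_end = 10.06, z_end = -5.03,
             flight_time = flight_time, gs_rel = 0.5, ...)
}

head_on_spec <- function(flight_time = 3, z_init = 25.16) {
  trajectory(z_init = z_init, x_end = 0, z_end = 0,
             flight_time = flight_time)
}

# Deterministic observer: every hyperprior width zero so a sampled
# participant has exactly the stated parameters. Caller overrides win.
noiseless_config <- function(...) {
  base <- list(
    tvis_base_early = c(1.0, 1.0), tvis_base_late = c(2.0, 2.0),
    tvis_gsrel_slope_sd = 0, tvis_sd_range = c(0, 0),
    beta_gain_sd = 0, beta_intercept_sd = 0, beta_noise_sd = 0,
    gammadot_gain_sd = 0, gammadot_intercept_sd = 0,
    gammadot_noise_sd = 0,
    response_sd0 = 0, decay_rate = 0, central_tendency_w = 0,
    response_bias_mean = 0, response_bias_sd = 0
  )
  do.call(simulation_config, utils::modifyList(base, list(...)))
}
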