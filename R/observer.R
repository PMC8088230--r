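#' Default configuration of the synthetic experiment
#'
#' One flat list holding every tunable of the synthetic-observer generator
#' and of the experimental session it emulates: 12 participants (7 "early
#' viewers" who uncover the ball before 1.5 s, 5 "late viewers"), 6 blocks
#' of 120 trials, five tailored trajectories presented 24 times per block
#' (20 test trials at 3 s and 4 control trials at 3.5 s, a 5:1 ratio) with
#' left/right mirrors balanced. Observer behaviour: a participant-specific
#' preferred viewing time weakly increasing with the trajectory's design
#' fraction; gaze at reappearance linearly coupled to the ball's angular
#' position; responses built from a per-participant strategy (`"gs"`
#' consumes the GS prediction at the prediction time t_visible + 0.2 s,
#' `"true_ttc"` responds around the true flight duration, `"constant_map"`
#' always maps to a fixed time), pulled toward the frequent 3-s duration
#' by a central-tendency weight, and perturbed by noise whose SD grows
#' with the time elapsed between prediction and response (prediction
#' decay). A response counts as a hit when it lands within +/- 50 ms of
#' the true flight duration.
#'
#' @param ... Named overrides of any default; unknown names are an error.
#' @return A named list of class `parattc_config`.
#' @examples
#' cfg <- simulation_config(n_participants = 2, blocks = 1)
#' @export
simulation_config <- function(...) {
  defaults <- list(
    seed = NULL,
    n_participants = 12,
    n_early = 7,
    blocks = 6,
    trials_main = 20,
    trials_control = 4,
    flight_time_main = 3,
    flight_time_control = 3.5,
    tvis_base_early = c(0.8, 1.3),
    tvis_base_late = c(1.7, 2.2),
    tvis_gsrel_slope_mean = 0.118,
    tvis_gsrel_slope_sd = 0.02,
    tvis_sd_range = c(0.1, 0.2),
    beta_gain_mean = 1.0,
    beta_gain_sd = 0.1,
    beta_intercept_sd = 1.0,
    beta_noise_sd = 2.0,
    gammadot_gain_mean = 1.0,
    gammadot_gain_sd = 0.15,
    gammadot_intercept_sd = 0.5,
    gammadot_noise_sd = 1.5,
    response_mode = "gs",
    response_constant = 3.0,
    response_sd0 = 0.05,
    decay_rate = 0.05,
    central_tendency_w = 0.15,
    response_bias_mean = 0.0,
    response_bias_sd = 0.05,
    frequent_duration = 3.0,
    prediction_latency = 0.2,
    hit_window = 0.05,
    p_correct_controller = 0.98,
    trajectory_source = "builtin",
    trajectory_file = NULL,
    out_dir = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "parattc_config_error")
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_early < 0 || cfg$n_early > cfg$n_participants) {
    abort("n_early must lie in [0, n_participants]",
          class = "parattc_config_error")
  }
  if (!cfg$response_mode %in% c("gs", "true_ttc", "constant_map")) {
    abort("response_mode must be one of gs, true_ttc, constant_map",
          class = "parattc_config_error")
  }
  if (cfg$central_tendency_w < 0 || cfg$central_tendency_w > 1) {
    abort("central_tendency_w must lie in [0, 1]",
          class = "parattc_config_error")
  }
  sds <- c("tvis_gsrel_slope_sd", "beta_gain_sd", "beta_intercept_sd",
           "beta_noise_sd", "gammadot_gain_sd", "gammadot_intercept_sd",
           "gammadot_noise_sd", "response_sd0", "decay_rate",
           "response_bias_sd")
  for (key in sds) {
    if (cfg[[key]] < 0) {
      abort(paste0(key, " must be >= 0"), class = "parattc_config_error")
    }
  }
  class(cfg) <- c("parattc_config", "list")
  cfg
}

#' Sample a cohort of synthetic observers
#'
#' Draws one parameter row per participant from the hyperpriors in the
#' configuration. The first `n_early` participants are early viewers
#' (preferred viewing baseline drawn from `tvis_base_early`), the rest
#' late viewers.
#'
#' @param n Number of participants.
#' @param config A [simulation_config()] list.
#' @param seed Optional integer; when supplied the draw is reproducible.
#' @return A tibble with one row per participant: identifiers, viewer
#'   class, viewing-time policy (`tvis_base`, `tvis_gsrel_slope`,
#'   `tvis_sd`), gaze coupling (gains, intercepts, noise SDs) and response
#'   strategy (`response_mode`, `response_constant`, `response_sd0`,
#'   `decay_rate`, `central_tendency_w`, `response_bias`).
#' @examples
#' sample_participants(3, simulation_config(n_early = 2), seed = 1)
#' @export
sample_participants <- function(n, config = simulation_config(),
                                seed = NULL) {
  if (n < 1) abort("n must be >= 1", class = "parattc_config_error")
  config <- validate_config(config)
  n_early <- min(config$n_early, n)
  if (!is.null(seed)) set.seed(seed)
  early <- seq_len(n) <= n_early
  base_range <- function(is_early) {
    lo <- ifelse(is_early, config$tvis_base_early[1],
                 config$tvis_base_late[1])
    hi <- ifelse(is_early, config$tvis_base_early[2],
                 config$tvis_base_late[2])
    runif(length(is_early), lo, hi)
  }
  tibble::tibble(
    participant_id = sprintf("s_%02d", seq_len(n)),
    viewer_class = ifelse(early, "early", "late"),
    tvis_base = base_range(early),
    tvis_gsrel_slope = rnorm(n, config$tvis_gsrel_slope_mean,
                             config$tvis_gsrel_slope_sd),
    tvis_sd = runif(n, config$tvis_sd_range[1], config$tvis_sd_range[2]),
    beta_gain = rnorm(n, config$beta_gain_mean, config$beta_gain_sd),
    beta_intercept = rnorm(n, 0, config$beta_intercept_sd),
    beta_noise_sd = rep(config$beta_noise_sd, n),
    gammadot_gain = rnorm(n, config$gammadot_gain_mean,
                          config$gammadot_gain_sd),
    gammadot_intercept = rnorm(n, 0, config$gammadot_intercept_sd),
    gammadot_noise_sd = rep(config$gammadot_noise_sd, n),
    response_mode = rep(config$response_mode, n),
    response_constant = rep(config$response_constant, n),
    response_sd0 = rep(config$response_sd0, n),
    decay_rate = rep(config$decay_rate, n),
    central_tendency_w = rep(config$central_tendency_w, n),
    response_bias = rnorm(n, config$response_bias_mean,
                          config$response_bias_sd)
  )
}

# Ball angular position (degrees) at arbitrary times, vectorised over rows
# that carry their own trajectory parameters. beta is measured from the
# initial line of sight on |x|, so it is mirror-invariant.
ball_angles_points <- function(z_init, x_end, z_end, flight_time, g, t) {
  vx <- x_end / flight_time
  vy0 <- g * flight_time / 2
  vz <- (z_end - z_init) / flight_time
  x <- vx * t
  y <- vy0 * t - g * t^2 / 2
  z <- z_init + vz * t
  tibble::tibble(
    beta_ball_deg = atan2(abs(x), z) * 180 / pi,
    gamma_ball_deg = atan(y / sqrt(x^2 + z^2)) * 180 / pi
  )
}

# Vectorised trial simulation for one participant over a prepared trial
# grid (one row per trial with the trajectory parameters joined in).
# Draws are column-wise in a fixed order so datasets are reproducible.
simulate_trials_for <- function(params, grid, config) {
  n <- nrow(grid)
  t_target <- params$tvis_base + params$tvis_gsrel_slope * grid$gs_rel
  t_visible <- rnorm(n, t_target, params$tvis_sd)
  t_visible <- pmin(pmax(t_visible, 0.5), grid$flight_time - 0.7)
  ang <- ball_angles_points(grid$z_init, grid$x_end, grid$z_end,
                            grid$flight_time, grid$g, t_visible)
  beta_gaze <- params$beta_gain * ang$beta_ball_deg +
    params$beta_intercept + rnorm(n, 0, params$beta_noise_sd)
  gamma_dot_gaze <- params$gammadot_gain * ang$gamma_ball_deg +
    params$gammadot_intercept + rnorm(n, 0, params$gammadot_noise_sd)
  t_pred <- t_visible + config$prediction_latency
  target <- switch(
    params$response_mode,
    gs = t_pred + gs_ttc_points(grid$z_init, grid$x_end, grid$z_end,
                                grid$flight_time, grid$g,
                                grid$ball_radius, t_pred),
    true_ttc = grid$flight_time,
    constant_map = rep(params$response_constant, n)
  )
  noise_sd <- pmax(params$response_sd0 +
                     params$decay_rate * (grid$flight_time - t_pred), 0)
  response <- (1 - params$central_tendency_w) * target +
    params$central_tendency_w * config$frequent_duration +
    params$response_bias + rnorm(n, 0, noise_sd)
  tibble::tibble(
    participant_id = rep(params$participant_id, n),
    block = grid$block,
    trial = grid$trial,
    traj_id = grid$traj_id,
    gs_rel = grid$gs_rel,
    side = grid$side,
    flight_time = grid$flight_time,
    t_visible = t_visible,
    beta_gaze_deg = beta_gaze,
    gamma_dot_gaze_deg_s = gamma_dot_gaze,
    beta_ball_deg = ang$beta_ball_deg,
    gamma_ball_deg = ang$gamma_ball_deg,
    response_time = response,
    hit = abs(response - grid$flight_time) <= config$hit_window,
    correct_controller = rbinom(n, 1, config$p_correct_controller) == 1
  )
}

#' Simulate a single trial
#'
#' One draw of the generative model for a given observer and trajectory:
#' the preferred viewing time is sampled and clamped to the feasible
#' window [0.5, T - 0.7] s, gaze at reappearance is linearly coupled to
#' the ball's angular position, and the response is assembled from the
#' participant's strategy, the central-tendency pull toward the frequent
#' duration, a constant bias, and prediction-decay noise. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param params A one-row participant tibble from [sample_participants()].
#' @param spec A one-row trajectory tibble.
#' @param config A [simulation_config()] list.
#' @return A one-row trial tibble (see [generate_dataset()] for columns).
#' @export
simulate_trial <- function(params, spec, config = simulation_config()) {
  stopifnot(nrow(params) == 1, nrow(spec) == 1)
  config <- validate_config(config)
  grid <- dplyr::mutate(spec, block = 1L, trial = 1L)
  simulate_trials_for(params, grid, config)
}

#' Generate a full synthetic trial dataset
#'
#' Builds the session layout (blocks x trajectories x durations x sides,
#' shuffled within block) and simulates every trial for every participant.
#' With the defaults: 12 participants x 6 blocks x 120 trials = 8640 rows,
#' each tailored trajectory presented 24 times per block (20 test trials
#' at 3 s, 4 control trials at 3.5 s), sides balanced. Fully reproducible
#' under `seed`.
#'
#' @param config A [simulation_config()] list.
#' @param trajectories Trajectory tibble containing, for every `gs_rel`,
#'   both flight durations and both sides (default the mirrored tailored
#'   set).
#' @param participants Optional participant tibble; sampled from `config`
#'   when `NULL`. An empty tibble yields an empty trial table.
#' @param seed Integer seed governing participants, trial order and all
#'   trial-level noise. Required unless both `config$seed` is set or
#'   `participants` is supplied and all noise is irrelevant.
#' @return A trial tibble with columns `participant_id`, `block`, `trial`,
#'   `traj_id`, `gs_rel`, `side`, `flight_time`, `t_visible`,
#'   `beta_gaze_deg`, `gamma_dot_gaze_deg_s`, `beta_ball_deg`,
#'   `gamma_ball_deg`, `response_time`, `hit`, `correct_controller`.
#' @examples
#' trials <- generate_dataset(simulation_config(n_participants = 2,
#'                                              n_early = 1, blocks = 1),
#'                            seed = 42)
#' @export
generate_dataset <- function(config = simulation_config(),
                             trajectories = experiment_trajectories(mirrored = TRUE),
                             participants = NULL,
                             seed = config$seed) {
  config <- validate_config(config)
  validate_trajectories(trajectories)
  if (is.null(seed)) {
    abort("a seed is required to generate data",
          class = "parattc_config_error")
  }
  set.seed(as.integer(seed))
  if (is.null(participants)) {
    participants <- sample_participants(config$n_participants, config)
  }
  if (nrow(participants) == 0) {
    empty <- simulate_trials_for(
      sample_participants(1, config),
      dplyr::mutate(trajectories[0, ], block = integer(), trial = integer()),
      config
    )
    return(empty)
  }
  block_layout <- function() {
    gs_levels <- sort(unique(trajectories$gs_rel))
    per_traj <- purrr::map_dfr(gs_levels, function(f) {
      tibble::tibble(
        gs_rel = f,
        flight_time = c(rep(config$flight_time_main, config$trials_main),
                        rep(config$flight_time_control,
                            config$trials_control)),
        side = c(rep(c("left", "right"), length.out = config$trials_main),
                 rep(c("left", "right"),
                     length.out = config$trials_control))
      )
    })
    per_traj[sample.int(nrow(per_traj)), ]
  }
  key <- trajectories[c("traj_id", "gs_rel", "side", "flight_time",
                        "z_init", "x_end", "z_end", "g", "ball_radius")]
  purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    grid <- purrr::map_dfr(seq_len(config$blocks), function(b) {
      lay <- block_layout()
      lay$block <- b
      lay$trial <- seq_len(nrow(lay))
      lay
    })
    grid <- dplyr::inner_join(
      grid, key, by = c("gs_rel", "side", "flight_time")
    )
    grid <- dplyr::arrange(grid, .data$block, .data$trial)
    simulate_trials_for(participants[i, ], grid, config)
  })
}
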