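# Duration indicator: 0 for the shortest (most frequent) flight time in
# the data, 1 otherwise, so mixed-model coefficients read as the mean
# difference in seconds between durations.
add_duration_indicator <- function(trials) {
  dplyr::mutate(trials,
                ttc = as.numeric(.data$flight_time >
                                   min(.data$flight_time)))
}

#' Filter response-time outliers with grouped 1.5 IQR fences
#'
#' Within each (participant, trajectory, flight duration) group, drops
#' trials whose response time falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Groups with fewer than 4 trials are
#' kept unfiltered with a warning.
#'
#' @param trials A trial tibble.
#' @return A list with `trials` (kept rows), `report` (one row per group:
#'   group keys, `n`, `n_removed`), `n_removed` and `pct_removed`.
#' @examples
#' trials <- generate_dataset(simulation_config(n_participants = 2,
#'                                              n_early = 1, blocks = 1),
#'                            seed = 3)
#' filtered <- filter_outliers(trials)
#' filtered$pct_removed
#' @export
filter_outliers <- function(trials) {
  grouped <- dplyr::group_by(trials, .data$participant_id, .data$traj_id,
                             .data$flight_time)
  flagged <- dplyr::mutate(grouped, .n_group = dplyr::n(), .outlier = {
    if (dplyr::n() < 4) {
      rep(FALSE, dplyr::n())
    } else {
      q <- quantile(.data$response_time, c(0.25, 0.75))
      iqr <- q[2] - q[1]
      .data$response_time < q[1] - 1.5 * iqr |
        .data$response_time > q[2] + 1.5 * iqr
    }
  })
  flagged <- dplyr::ungroup(flagged)
  n_small <- sum(flagged$.n_group < 4)
  if (n_small > 0) {
    warn(sprintf("%d trial(s) in groups of < 4 trials left unfiltered",
                 n_small))
  }
  report <- dplyr::summarise(
    dplyr::group_by(flagged, .data$participant_id, .data$traj_id,
                    .data$flight_time),
    n = dplyr::n(),
    n_removed = sum(.data$.outlier),
    .groups = "drop"
  )
  kept <- dplyr::select(flagged[!flagged$.outlier, ],
                        -dplyr::all_of(c(".outlier", ".n_group")))
  n_removed <- sum(flagged$.outlier)
  list(
    trials = kept,
    report = report,
    n_removed = n_removed,
    pct_removed = 100 * n_removed / max(nrow(trials), 1)
  )
}

#' Gaze-prediction analysis
#'
#' Did observers predict the ball's position while it was occluded?
#' Horizontal gaze direction at reappearance is regressed on the ball's
#' horizontal angle, and the vertical gaze rate on the ball's elevation
#' angle, each with a participant random intercept, and each compared by
#' likelihood-ratio test against the intercept-only null. Per-participant
#' ordinary least-squares slopes are returned for plotting.
#'
#' @param trials A trial tibble.
#' @return A list with `horizontal` and `vertical` (each: `model`, `null`,
#'   `lrt`) and `participant_slopes` (tibble: participant, axis, slope,
#'   intercept).
#' @export
gaze_prediction_analysis <- function(trials) {
  fit_axis <- function(resp, pred) {
    model <- fit_random_intercept_lmm(trials, resp, pred)
    null <- fit_random_intercept_lmm(trials, resp, NULL)
    list(model = model, null = null,
         lrt = likelihood_ratio_test(null, model))
  }
  slopes <- purrr::map_dfr(
    list(c("beta_gaze_deg", "beta_ball_deg", "horizontal"),
         c("gamma_dot_gaze_deg_s", "gamma_ball_deg", "vertical")),
    function(ax) {
      dplyr::summarise(
        dplyr::group_by(trials, .data$participant_id),
        axis = ax[3],
        slope = coef(lm(.data[[ax[1]]] ~ .data[[ax[2]]]))[2],
        intercept = coef(lm(.data[[ax[1]]] ~ .data[[ax[2]]]))[1],
        .groups = "drop"
      )
    }
  )
  list(
    horizontal = fit_axis("beta_gaze_deg", "beta_ball_deg"),
    vertical = fit_axis("gamma_dot_gaze_deg_s", "gamma_ball_deg"),
    participant_slopes = slopes
  )
}

#' Preferred viewing-time analysis
#'
#' Does the moment observers choose to uncover the ball depend on the
#' trajectory and/or the flight duration? Fits
#' `t_visible ~ ttc * gs_rel + (1 | participant)` (duration as a 0/1
#' indicator, design fraction as a numeric fraction) against the
#' intercept-only null, and summarises mean viewing time per participant,
#' duration and trajectory.
#'
#' @param trials A trial tibble.
#' @return A list with `model`, `null`, `lrt` and `summary` (per
#'   participant x flight_time x gs_rel mean and SD of `t_visible`).
#' @export
viewing_time_analysis <- function(trials) {
  trials <- add_duration_indicator(trials)
  model <- fit_random_intercept_lmm(trials, "t_visible", "ttc * gs_rel")
  null <- fit_random_intercept_lmm(trials, "t_visible", NULL)
  summary_tbl <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$flight_time,
                    .data$gs_rel),
    mean_t_visible = mean(.data$t_visible),
    sd_t_visible = sd(.data$t_visible),
    .groups = "drop"
  )
  list(model = model, null = null,
       lrt = likelihood_ratio_test(null, model), summary = summary_tbl)
}

#' Response-time analysis
#'
#' Does response time differ between flight durations (ruling out a fixed
#' response criterion)? Fits `response_time ~ ttc + (1 | participant)`
#' with duration as a 0/1 indicator -- so the coefficient is the mean
#' response-time difference in seconds between the 3.5-s and 3-s flights
#' and the intercept the mean response time for 3-s flights -- and
#' compares it against the intercept-only null.
#'
#' @param trials A trial tibble.
#' @return A list with `model`, `null` and `lrt`.
#' @export
response_time_analysis <- function(trials) {
  trials <- add_duration_indicator(trials)
  model <- fit_random_intercept_lmm(trials, "response_time", "ttc")
  null <- fit_random_intercept_lmm(trials, "response_time", NULL)
  list(model = model, null = null,
       lrt = likelihood_ratio_test(null, model))
}

#' Correspondence between responses and GS-model predictions
#'
#' At each trial's prediction time (midpoint of the visibility window,
#' `t_visible` + `latency`), computes the GS-model predicted remaining
#' TTC and the observed remaining response time
#' (`response_time - t_pred`), fits a Deming regression of the latter on
#' the former per participant and trajectory, bootstraps the pooled mean
#' slope over participants, and fits an across-trajectory mixed model of
#' the remaining response time on the design fraction.
#'
#' @param trials A trial tibble.
#' @param trajectories Trajectory tibble with the `traj_id`s present in
#'   `trials`.
#' @param variance_ratio Deming error-variance ratio (default 1,
#'   orthogonal).
#' @param n_boot Bootstrap resamples for the pooled-slope CI
#'   (default 1000).
#' @param latency Prediction latency after reappearance, seconds
#'   (default 0.2).
#' @return A list with `fits` (per participant x trajectory slopes),
#'   `pooled_slope`, `pooled_ci` (percentile 95% CI), and `model` (the
#'   across-trajectory `ttc_lmm` of remaining response time on `gs_rel`).
#' @export
correspondence_analysis <- function(trials, trajectories,
                                    variance_ratio = 1, n_boot = 1000,
                                    latency = 0.2) {
  key <- trajectories[c("traj_id", "z_init", "x_end", "z_end",
                        "flight_time", "g", "ball_radius")]
  joined <- dplyr::inner_join(trials, key,
                              by = c("traj_id", "flight_time"))
  if (nrow(joined) != nrow(trials)) {
    abort("trials contain traj_ids absent from the trajectory table",
          class = "parattc_validation_error")
  }
  joined <- dplyr::mutate(
    joined,
    t_pred = .data$t_visible + latency,
    gs_pred = gs_ttc_points(.data$z_init, .data$x_end, .data$z_end,
                            .data$flight_time, .data$g,
                            .data$ball_radius, .data$t_pred),
    remaining_response = .data$response_time - .data$t_pred
  )
  fits <- dplyr::group_modify(
    dplyr::group_by(joined, .data$participant_id, .data$gs_rel),
    function(df, key) {
      fit <- tryCatch(
        deming_regression(df, "gs_pred", "remaining_response",
                          variance_ratio),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        tibble::tibble(slope = NA_real_, intercept = NA_real_,
                       n = nrow(df))
      } else {
        tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                       n = fit$n)
      }
    }
  )
  fits <- dplyr::ungroup(fits)
  ok <- fits[is.finite(fits$slope), ]
  ids <- unique(ok$participant_id)
  boot_means <- vapply(seq_len(n_boot), function(i) {
    take <- sample(ids, length(ids), replace = TRUE)
    mean(unlist(lapply(take, function(id) {
      ok$slope[ok$participant_id == id]
    })))
  }, numeric(1))
  model <- fit_random_intercept_lmm(joined, "remaining_response",
                                    "gs_rel")
  list(
    fits = fits,
    pooled_slope = mean(ok$slope),
    pooled_ci = unname(quantile(boot_means, c(0.025, 0.975))),
    model = model
  )
}

#' Proximity-to-privileged-time split
#'
#' Splits trials per participant and trajectory at the median absolute
#' distance between the prediction time and the trajectory's privileged
#' zero-error time ("closer" vs "far"; ties go to closer), and compares
#' the mean signed temporal error (`response_time - flight_time`) between
#' the halves with a Welch t-test.
#'
#' @param trials A trial tibble.
#' @param trajectories Trajectory tibble covering the `traj_id`s in
#'   `trials`.
#' @param latency Prediction latency after reappearance, seconds.
#' @return A list with `closer_mean`, `far_mean` (seconds), `t_test`
#'   (one-row tibble: statistic, df, p_value) and `by_group` means.
#' @export
proximity_split_analysis <- function(trials, trajectories,
                                     latency = 0.2) {
  priv <- tibble::tibble(
    traj_id = trajectories$traj_id,
    t_privileged = privileged_time(trajectories)
  )
  joined <- dplyr::inner_join(trials, priv, by = "traj_id")
  if (nrow(joined) != nrow(trials)) {
    abort("trials contain traj_ids absent from the trajectory table",
          class = "parattc_validation_error")
  }
  joined <- dplyr::mutate(
    joined,
    distance = abs(.data$t_visible + latency - .data$t_privileged),
    signed_error = .data$response_time - .data$flight_time
  )
  joined <- dplyr::mutate(
    dplyr::group_by(joined, .data$participant_id, .data$gs_rel),
    split = ifelse(.data$distance <= median(.data$distance),
                   "closer", "far")
  )
  joined <- dplyr::ungroup(joined)
  by_group <- dplyr::summarise(
    dplyr::group_by(joined, .data$participant_id, .data$gs_rel,
                    .data$split),
    mean_error = mean(.data$signed_error),
    n = dplyr::n(),
    .groups = "drop"
  )
  tt <- t.test(signed_error ~ split, data = joined)
  list(
    closer_mean = mean(joined$signed_error[joined$split == "closer"]),
    far_mean = mean(joined$signed_error[joined$split == "far"]),
    t_test = tibble::tibble(
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    ),
    by_group = by_group
  )
}

#' Per-participant performance metrics
#'
#' Hit probability (response within +/- 50 ms of the true flight
#' duration), response-time SD, mean response time and mean time elapsed
#' between prediction and response, per participant and flight duration;
#' plus the early/late viewer classification (mean viewing time below or
#' above 1.5 s).
#'
#' @param trials A trial tibble.
#' @param latency Prediction latency after reappearance, seconds.
#' @return A list with `by_participant` (mean viewing time and viewer
#'   class) and `by_duration` (per participant x flight duration:
#'   `hit_prob`, `rt_sd`, `mean_rt`, `mean_time_since_pred`, joined with
#'   the viewer class).
#' @export
performance_metrics <- function(trials, latency = 0.2) {
  by_participant <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id),
    mean_t_visible = mean(.data$t_visible),
    .groups = "drop"
  )
  by_participant$viewer_class <-
    ifelse(by_participant$mean_t_visible < 1.5, "early", "late")
  by_duration <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$flight_time),
    hit_prob = mean(.data$hit),
    rt_sd = sd(.data$response_time),
    mean_rt = mean(.data$response_time),
    mean_time_since_pred = mean(.data$response_time -
                                  (.data$t_visible + latency)),
    .groups = "drop"
  )
  by_duration <- dplyr::left_join(
    by_duration,
    by_participant[c("participant_id", "viewer_class")],
    by = "participant_id"
  )
  list(by_participant = by_participant, by_duration = by_duration)
}
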