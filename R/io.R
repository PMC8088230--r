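trial_csv_columns <- c(
  "participant_id", "block", "trial", "traj_id", "gs_rel", "side",
  "flight_time", "t_visible", "beta_gaze_deg", "gamma_dot_gaze_deg_s",
  "beta_ball_deg", "gamma_ball_deg", "response_time", "hit",
  "correct_controller"
)

trial_time_columns <- c("t_visible", "response_time")
trial_real_columns <- c("gs_rel", "flight_time", "t_visible",
                        "beta_gaze_deg", "gamma_dot_gaze_deg_s",
                        "beta_ball_deg", "gamma_ball_deg",
                        "response_time")

#' Read and write trial tables
#'
#' The package's canonical interchange format: a CSV with exactly the
#' trial-record header. Times are serialized at microsecond precision and
#' the boolean columns (`hit`, `correct_controller`) as 0/1. Reading
#' validates the header and refuses truncated rows, naming the offending
#' column.
#'
#' @param trials A trial tibble (see [generate_dataset()]).
#' @param path File path.
#' @return `read_trials()` returns a trial tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_csv_columns, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "parattc_format_error")
  }
  out <- trials[trial_csv_columns]
  for (col in trial_time_columns) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  out$hit <- as.integer(out$hit)
  out$correct_controller <- as.integer(out$correct_controller)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      traj_id = readr::col_character(),
      side = readr::col_character(),
      hit = readr::col_integer(),
      correct_controller = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  missing <- setdiff(trial_csv_columns, names(raw))
  if (length(missing) > 0) {
    abort(paste0("trial CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "parattc_format_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed trial CSV at row(s): ",
                 paste(unique(probs$row), collapse = ", ")),
          class = "parattc_format_error")
  }
  if (anyNA(raw[trial_csv_columns])) {
    bad <- trial_csv_columns[vapply(raw[trial_csv_columns], anyNA,
                                    logical(1))]
    abort(paste0("missing values in column(s): ",
                 paste(bad, collapse = ", ")),
          class = "parattc_format_error")
  }
  out <- tibble::as_tibble(raw[trial_csv_columns])
  out$hit <- out$hit == 1L
  out$correct_controller <- out$correct_controller == 1L
  out
}

#' Load and save run configurations
#'
#' Configurations are flat key-value YAML files mirroring
#' [simulation_config()]. Unknown keys are rejected; an empty file yields
#' all defaults. `write_config()` round-trips losslessly.
#'
#' @param path File path.
#' @param config A [simulation_config()] list.
#' @return `load_config()` returns a validated `parattc_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "parattc_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(simulation_config, raw)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
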