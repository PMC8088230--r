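#' Run the full synthetic experiment and analysis pipeline
#'
#' End-to-end orchestration: builds (or loads) the tailored trajectory
#' set, verifies its privileged zero-error times, samples a cohort of
#' synthetic observers, generates the trial dataset, applies the grouped
#' IQR outlier filter, and runs every analysis (gaze prediction, viewing
#' time, response time, GS correspondence, proximity split, performance
#' metrics). When `out_dir` is given, a self-describing report bundle is
#' written: the config echo, seed and package version, plus
#' `trajectories.csv`, `privileged_times.csv`, `trials.csv`,
#' `filtered.csv`, `outlier_report.csv`, `lmm_results.csv`,
#' `lrt_results.csv`, `deming_fits.csv` and `metrics.csv`. All outputs
#' are deterministic under the seed. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [simulation_config()] list; `config$seed` must be set.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param n_boot Bootstrap resamples for the correspondence pooled slope.
#' @return (Invisibly) a list with `trajectories`, `privileged_times`,
#'   `participants`, `trials`, `filtered`, and the analysis results
#'   (`gaze`, `viewing_time`, `response_time`, `correspondence`,
#'   `proximity`, `metrics`).
#' @examples
#' \donttest{
#' res <- run_experiment(simulation_config(seed = 1, n_participants = 4,
#'                                         n_early = 2, blocks = 1))
#' }
#' @export
run_experiment <- function(config, out_dir = config$out_dir,
                           n_boot = 1000) {
  config <- validate_config(config)
  if (is.null(config$seed)) {
    abort("config$seed is required for a reproducible run",
          class = "parattc_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "parattc_stage_error")
    })
  }

  trajectories <- stage("trajectories", {
    if (identical(config$trajectory_source, "file")) {
      read_trajectories(config$trajectory_file)
    } else {
      experiment_trajectories(mirrored = TRUE)
    }
  })
  privileged <- stage("verify_privileged_times", {
    tibble::tibble(
      traj_id = trajectories$traj_id,
      gs_rel = trajectories$gs_rel,
      flight_time = trajectories$flight_time,
      t_privileged = privileged_time(trajectories),
      fraction = privileged_time(trajectories) / trajectories$flight_time
    )
  })
  set.seed(as.integer(config$seed))
  participants <- stage("participants", {
    sample_participants(config$n_participants, config)
  })
  trials <- stage("generate", {
    generate_dataset(config, trajectories, participants,
                     seed = config$seed)
  })
  filtered <- stage("filter_outliers", filter_outliers(trials))
  gaze <- stage("gaze_analysis", gaze_prediction_analysis(filtered$trials))
  viewing <- stage("viewing_time_analysis",
                   viewing_time_analysis(filtered$trials))
  response <- stage("response_time_analysis",
                    response_time_analysis(filtered$trials))
  correspondence <- stage("correspondence_analysis",
                          correspondence_analysis(filtered$trials,
                                                  trajectories,
                                                  n_boot = n_boot))
  proximity <- stage("proximity_split_analysis",
                     proximity_split_analysis(filtered$trials,
                                              trajectories))
  metrics <- stage("performance_metrics",
                   performance_metrics(filtered$trials))

  results <- list(
    config = config,
    trajectories = trajectories,
    privileged_times = privileged,
    participants = participants,
    trials = trials,
    filtered = filtered,
    gaze = gaze,
    viewing_time = viewing,
    response_time = response,
    correspondence = correspondence,
    proximity = proximity,
    metrics = metrics
  )
  if (!is.null(out_dir)) {
    stage("write_bundle", write_report_bundle(results, out_dir))
  }
  invisible(results)
}

collect_lmm_rows <- function(results) {
  models <- list(
    gaze_horizontal = results$gaze$horizontal$model,
    gaze_vertical = results$gaze$vertical$model,
    viewing_time = results$viewing_time$model,
    response_time = results$response_time$model,
    correspondence = results$correspondence$model
  )
  purrr::map_dfr(names(models), function(nm) {
    dplyr::mutate(tidy(models[[nm]]), analysis = nm, .before = 1)
  })
}

collect_lrt_rows <- function(results) {
  lrts <- list(
    gaze_horizontal = results$gaze$horizontal$lrt,
    gaze_vertical = results$gaze$vertical$lrt,
    viewing_time = results$viewing_time$lrt,
    response_time = results$response_time$lrt
  )
  purrr::map_dfr(names(lrts), function(nm) {
    dplyr::mutate(tibble::as_tibble(lrts[[nm]]), analysis = nm,
                  .before = 1)
  })
}

write_report_bundle <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_config(results$config, p("config.yaml"))
  writeLines(
    c(sprintf("parattc version: %s", packageVersion("parattc")),
      sprintf("seed: %d", as.integer(results$config$seed))),
    p("run_info.txt")
  )
  write_trajectories(results$trajectories, p("trajectories.csv"))
  readr::write_csv(results$privileged_times, p("privileged_times.csv"))
  write_trials(results$trials, p("trials.csv"))
  write_trials(results$filtered$trials, p("filtered.csv"))
  readr::write_csv(results$filtered$report, p("outlier_report.csv"))
  readr::write_csv(collect_lmm_rows(results), p("lmm_results.csv"))
  readr::write_csv(collect_lrt_rows(results), p("lrt_results.csv"))
  readr::write_csv(results$correspondence$fits, p("deming_fits.csv"))
  readr::write_csv(results$metrics$by_duration, p("metrics.csv"))
  invisible(out_dir)
}
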