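test_that("participant sampling honours class mix and seed", {
  cfg <- simulation_config()
  p <- sample_participants(12, cfg, seed = 5)
  expect_identical(sum(p$viewer_class == "early"), 7L)
  expect_identical(sum(p$viewer_class == "late"), 5L)
  expect_true(all(p$tvis_base[p$viewer_class == "early"] < 1.5))
  expect_true(all(p$tvis_base[p$viewer_class == "late"] > 1.5))

  expect_identical(sample_participants(4, cfg, seed = 9),
                   sample_participants(4, cfg, seed = 9))

  all_late <- simulation_config(n_early = 0)
  expect_true(all(sample_participants(12, all_late,
                                      seed = 1)$viewer_class == "late"))
  expect_error(simulation_config(n_early = 13),
               class = "parattc_config_error")
  expect_error(simulation_config(nonsense_key = 1),
               class = "parattc_config_error")
})

test_that("noise-free responders behave as their strategy dictates", {
  specs <- experiment_trajectories()
  s3 <- specs[specs$gs_rel == 0.5 & specs$flight_time == 3, ]
  s35 <- specs[specs$gs_rel == 0.5 & specs$flight_time == 3.5, ]

  cfg <- noiseless_config(response_mode = "true_ttc")
  p <- sample_participants(1, cfg, seed = 1)
  tr <- simulate_trial(p, s3, cfg)
  expect_equal(tr$response_time, 3)
  expect_true(tr$hit)

  cfg_const <- noiseless_config(response_mode = "constant_map",
                                response_constant = 3.0)
  p_const <- sample_participants(1, cfg_const, seed = 1)
  r3 <- simulate_trial(p_const, s3, cfg_const)$response_time
  r35 <- simulate_trial(p_const, s35, cfg_const)$response_time
  expect_equal(r3, r35)
  expect_equal(r3, 3.0)

  # GS-strategy responder consumes the model prediction at t_pred
  cfg_gs <- noiseless_config(response_mode = "gs",
                             tvis_base_early = c(0.75, 0.75),
                             tvis_gsrel_slope_mean = 0)
  p_gs <- sample_participants(1, cfg_gs, seed = 1)
  tr_gs <- simulate_trial(p_gs, s3, cfg_gs)
  expect_equal(tr_gs$t_visible, 0.75)
  expect_equal(tr_gs$response_time,
               0.95 + oracle_gs_ttc(25.16, 10.06, -5.03, 3, 0.95),
               tolerance = 1e-4)
})

test_that("central tendency pulls responses toward the frequent duration", {
  cfg <- noiseless_config(response_mode = "true_ttc",
                          central_tendency_w = 0.4)
  p <- sample_participants(1, cfg, seed = 1)
  s35 <- experiment_trajectories()[2, ]
  stopifnot(s35$flight_time == 3.5)
  expect_equal(simulate_trial(p, s35, cfg)$response_time,
               0.6 * 3.5 + 0.4 * 3.0)
})

test_that("viewing times stay inside the feasible window", {
  cfg <- simulation_config(tvis_base_early = c(0.1, 0.1),
                           tvis_base_late = c(3.4, 3.4),
                           tvis_sd_range = c(0.3, 0.3))
  trials <- generate_dataset(simulation_config(), seed = 2,
                             participants = sample_participants(4, cfg,
                                                                seed = 2))
  expect_true(all(trials$t_visible >= 0.5))
  expect_true(all(trials$t_visible <= trials$flight_time - 0.7))
})

test_that("the default session layout reproduces the trial arithmetic", {
  trials <- generate_dataset(simulation_config(), seed = 20)
  expect_identical(nrow(trials), 8640L)
  expect_identical(sum(trials$flight_time == 3.5), 1440L)
  expect_identical(unname(table(trials$participant_id))[1], 720L)

  per_block <- dplyr::count(trials, participant_id, block, gs_rel, flight_time)
  expect_true(all(per_block$n[per_block$flight_time == 3] == 20))
  expect_true(all(per_block$n[per_block$flight_time == 3.5] == 4))

  sides <- dplyr::count(trials, gs_rel, flight_time, side)
  expect_true(all(sides$n[sides$flight_time == 3] == 12 * 6 * 10))
  expect_true(all(sides$n[sides$flight_time == 3.5] == 12 * 6 * 2))

  expect_true(all(trials$hit ==
                    (abs(trials$response_time - trials$flight_time) <=
                       0.05)))
})

test_that("dataset generation is reproducible and seed-gated", {
  a <- generate_dataset(simulation_config(n_participants = 2, n_early = 1,
                                          blocks = 1), seed = 31)
  b <- generate_dataset(simulation_config(n_participants = 2, n_early = 1,
                                          blocks = 1), seed = 31)
  expect_identical(a, b)
  expect_error(generate_dataset(simulation_config()),
               class = "parattc_config_error")

  cfg <- simulation_config()
  empty <- generate_dataset(cfg, seed = 1,
                            participants = sample_participants(1, cfg)[0, ])
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(a))
})

test_that("generated gaze recovers the configured coupling gains", {
  cfg <- simulation_config(beta_gain_mean = 0.8, beta_gain_sd = 0,
                           beta_intercept_sd = 0,
                           gammadot_gain_mean = 1.2, gammadot_gain_sd = 0,
                           gammadot_intercept_sd = 0)
  trials <- generate_dataset(cfg, seed = 12)
  h <- lm(beta_gaze_deg ~ beta_ball_deg, data = trials)
  v <- lm(gamma_dot_gaze_deg_s ~ gamma_ball_deg, data = trials)
  expect_equal(unname(coef(h)[2]), 0.8,
               tolerance = 3 * summary(h)$coefficients[2, 2] / 0.8)
  expect_equal(unname(coef(v)[2]), 1.2,
               tolerance = 3 * summary(v)$coefficients[2, 2] / 1.2)
})
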