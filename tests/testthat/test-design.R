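test_that("inverse design recovers the printed launch depths", {
  fixed <- list(
    list(f = 0.3, x_end = 15.09, z_end = -4.53, z_init = 23.49),
    list(f = 0.4, x_end = 12.53, z_end = -5.01, z_init = 24.23),
    list(f = 0.5, x_end = 10.06, z_end = -5.03, z_init = 25.16),
    list(f = 0.6, x_end = 7.71, z_end = -4.63, z_init = 26.24),
    list(f = 0.7, x_end = 5.53, z_end = -3.87, z_init = 27.47)
  )
  for (case in fixed) {
    spec <- design_trajectory(case$f, flight_time = 3,
                              fixed = c(x_end = case$x_end,
                                        z_end = case$z_end),
                              interval = c(10, 40))
    expect_equal(spec$z_init, case$z_init, tolerance = 0.1 / case$z_init)
  }
})

test_that("designed trajectories round-trip through privileged_time", {
  for (f in c(0.35, 0.45, 0.55, 0.65)) {
    for (T in c(3, 3.5)) {
      spec <- design_trajectory(f, flight_time = T,
                                fixed = c(x_end = 10, z_end = -5),
                                interval = c(5, 50))
      expect_equal(privileged_time(spec), f * T, tolerance = 1e-3 / (f * T))
    }
  }
})

test_that("any endpoint parameter can be freed", {
  spec <- design_trajectory(0.5, 3,
                            fixed = c(z_init = 25.16, z_end = -5.03),
                            free = "x_end", interval = c(1, 30))
  expect_equal(spec$x_end, 10.06, tolerance = 0.01)

  spec2 <- design_trajectory(0.5, 3,
                             fixed = c(z_init = 25.16, x_end = 10.06),
                             free = "z_end", interval = c(-20, 0))
  expect_equal(spec2$z_end, -5.03, tolerance = 0.01)
})

test_that("infeasible designs raise a design error", {
  # head-on geometry: the GS model is exact throughout, no crossing
  expect_error(
    design_trajectory(0.5, 3, fixed = c(x_end = 0, z_end = 0),
                      interval = c(10, 40)),
    class = "parattc_design_infeasible_error"
  )
  expect_error(
    design_trajectory(1.2, 3, fixed = c(x_end = 10, z_end = -5)),
    class = "parattc_validation_error"
  )
  expect_error(
    design_trajectory(0.5, 3, fixed = c(x_end = 10)),
    class = "parattc_validation_error"
  )
})

test_that("the tailored experimental set matches its printed layout", {
  specs <- experiment_trajectories()
  expect_identical(nrow(specs), 10L)
  expect_identical(nrow(experiment_trajectories(mirrored = TRUE)), 20L)
  expect_setequal(specs$flight_time, c(3, 3.5))

  fifth <- specs[specs$gs_rel == 0.7 & specs$flight_time == 3, ]
  expect_equal(fifth$z_init, 27.47)
  expect_equal(fifth$x_end, 5.53)
  expect_equal(fifth$z_end, -3.87)

  t3 <- specs[specs$flight_time == 3, ]
  expect_equal(privileged_time(t3), c(0.9, 1.2, 1.5, 1.8, 2.1),
               tolerance = 0.05 / 0.9)
  t35 <- specs[specs$flight_time == 3.5, ]
  expect_equal(privileged_time(t35), c(1.05, 1.4, 1.75, 2.1, 2.45),
               tolerance = 0.05 / 1.05)
})
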