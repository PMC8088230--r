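test_that("launch velocity matches the closed-form endpoint conditions", {
  v <- launch_velocity(mid_spec())
  expect_equal(v$vy0, 9.807 * 3 / 2, tolerance = 1e-12)
  expect_equal(v$vz, (-5.03 - 25.16) / 3, tolerance = 1e-12)
  expect_equal(v$vx, 10.06 / 3, tolerance = 1e-12)

  head_on <- launch_velocity(head_on_spec())
  expect_equal(head_on$vx, 0)
  expect_equal(head_on$vz, -25.16 / 3, tolerance = 1e-12)

  left <- launch_velocity(mid_spec(side = "left"))
  expect_equal(left$vx, -10.06 / 3, tolerance = 1e-12)

  # height returns to zero exactly at t = T for any spec
  specs <- experiment_trajectories()
  for (i in seq_len(nrow(specs))) {
    end <- ball_state(specs[i, ], specs$flight_time[i])
    expect_equal(end$y, 0, tolerance = 1e-10)
    expect_equal(end$x, specs$x_end[i], tolerance = 1e-10)
    expect_equal(end$z, specs$z_end[i], tolerance = 1e-10)
  }
})

test_that("ball state is standard projectile kinematics", {
  spec <- mid_spec()
  start <- ball_state(spec, 0)
  expect_equal(c(start$x, start$y, start$z), c(0, 0, 25.16))

  apex <- ball_state(spec, 1.5)
  expect_equal(apex$y, 9.807 * 9 / 8, tolerance = 1e-12)
  expect_equal(apex$vy, 0, tolerance = 1e-12)

  # height profile symmetric about T/2
  t <- seq(0, 1.5, by = 0.05)
  expect_equal(ball_state(spec, t)$y, ball_state(spec, 3 - t)$y,
               tolerance = 1e-10)

  expect_error(ball_state(spec, 3.2), class = "parattc_range_error")
  expect_error(ball_state(spec, -0.1), class = "parattc_range_error")
})

test_that("trapezoid-integrated velocity reproduces closed-form position", {
  spec <- mid_spec(flight_time = 3.5)
  t <- seq(0, 3.5, by = 0.001)
  st <- ball_state(spec, t)
  integ <- function(v0, deriv) {
    v0 + c(0, cumsum((deriv[-1] + deriv[-length(deriv)]) / 2 * diff(t)))
  }
  expect_equal(integ(0, st$vx), st$x, tolerance = 1e-9)
  expect_equal(integ(0, st$vy), st$y, tolerance = 1e-9)
  expect_equal(integ(25.16, st$vz), st$z, tolerance = 1e-9)
})

test_that("ground track matches hand-evaluated values and is mirror invariant", {
  gt <- ground_track(mid_spec(), c(0, 0.5, 1))
  expect_equal(gt$rho[1], 25.16)
  expect_equal(gt$rho[3], sqrt(10.06^2 + 5.03^2), tolerance = 1e-12)
  expect_equal(gt$rho[2], 11.252, tolerance = 1e-3)
  expect_equal(gt$drho_dtau[2], -22.508, tolerance = 1e-3)

  tau <- seq(0, 1, by = 0.01)
  expect_equal(ground_track(mid_spec(side = "left"), tau)$rho,
               ground_track(mid_spec(side = "right"), tau)$rho)
})

test_that("trajectory validation rejects impossible specs", {
  expect_error(trajectory(25, 10, -5, flight_time = -1),
               class = "parattc_validation_error")
  expect_error(trajectory(-2, 10, -5, flight_time = 3),
               class = "parattc_validation_error")
  expect_error(trajectory(25, -1, -5, flight_time = 3),
               class = "parattc_validation_error")
  expect_error(trajectory(25, 10, -5, 3, side = "up"),
               class = "parattc_validation_error")
})

test_that("trajectory CSV round trip is lossless", {
  path <- withr::local_tempfile(fileext = ".csv")
  specs <- experiment_trajectories(mirrored = TRUE)
  write_trajectories(specs, path)
  back <- read_trajectories(path)
  expect_equal(as.data.frame(back), as.data.frame(specs))

  header_only <- readr::read_lines(path, n_max = 1)
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(sub("z_init_m", "zi", header_only), bad)
  expect_error(read_trajectories(bad), class = "parattc_format_error")
})
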