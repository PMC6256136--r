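# Forward-dynamics generator: course statistics, race dynamics, energy
# conservation, sensor synthesis, determinism.

test_that("generated courses realize the requested climb statistics", {
  course <- default_course()
  z <- course$z
  expect_equal(diff(range(z)), 51, tolerance = 0.02)
  dz <- diff(c(z, z[1]))
  expect_equal(sum(pmax(dz, 0)), 166, tolerance = 0.02)
  expect_equal(attr(course, "lap_length"), 4500, tolerance = 0.02)
  # arc-length spacing and chord consistency
  expect_true(all(abs(diff(course$s) - 1) < 0.5))
  chord <- sqrt(diff(course$x)^2 + diff(course$y)^2 + diff(course$z)^2)
  expect_lt(max(abs(chord - diff(course$s))), 0.01)
  expect_true(any(course$fix_quality == "float"))
})

test_that("flat course specs give zero elevation and infeasible specs error", {
  flat <- generate_course(course_spec(lap_length = 1000, height_diff = 0,
                                      total_climb = 0, n_float = 0))
  expect_true(all(flat$z == 0))
  expect_error(course_spec(height_diff = 51, total_climb = 30), "infeasible")
})

test_that("course generation is deterministic in the seed", {
  c1 <- generate_course(course_spec(lap_length = 1000, height_diff = 10,
                                    total_climb = 30, seed = 5))
  c2 <- generate_course(course_spec(lap_length = 1000, height_diff = 10,
                                    total_climb = 30, seed = 5))
  expect_identical(c1$x, c2$x)
  expect_identical(c1$fix_quality, c2$fix_quality)
})

test_that("coasting on a closed loop conserves mechanical energy", {
  course <- small_course()
  ath <- athlete_model(crr = 1e-9)
  pol <- power_policy(intercept = 0, slope_v = 0, slope_vdot = 0,
                      tuck_enter = 1e9)
  par <- drag_model_params(A_equip = 0)
  par$beta <- c(0, 0, 0)  # zero frontal area: no drag
  env <- environment_record()
  truth <- simulate_race(course, ath, pol, env, par, v0 = 12, laps = 1)
  E <- 0.5 * truth$speed^2 + 9.81 * truth$z
  expect_lt(diff(range(E)) / E[1], 1e-4)
})

test_that("constant power on a constant grade converges to the analytic steady state", {
  # long straight slight climb, no turns
  n <- 3000
  course <- reference_track(0:n, (0:n) / sqrt(1 + 0.02^2), rep(0, n + 1),
                            0.02 * (0:n) / sqrt(1 + 0.02^2))
  # close the loop artificially for the geometry helper
  attr(course, "closed") <- TRUE
  attr(course, "lap_length") <- n + 1
  ath <- athlete_model()
  pol <- power_policy(slope_v = -0.54, slope_vdot = 0, intercept = 7.26,
                      tuck_enter = 1e9)
  env <- environment_record()  # zero wind
  par <- drag_model_params()
  truth <- simulate_race(course, ath, pol, env, par, v0 = 5, laps = 1)
  mid <- truth$s_total > 1500 & truth$s_total < 2500
  atm <- atmosphere(env$temp_C, env$pressure_kPa)
  post <- posture_schedule(FALSE, 0.02)
  A <- frontal_area_imu(post$theta_torso, post$theta_thigh, par)
  v_eq <- mean(truth$speed[mid])
  Re <- reynolds(v_eq, par$L, atm$rho, atm$mu)
  ACD <- A * drag_coefficient(Re, par)
  v_pred <- steady_state_speed(atan(0.02), pol, ath$mass_kg, ACD, ath$crr,
                               atm$rho)
  expect_equal(v_eq, v_pred, tolerance = 1e-3)
})

test_that("the default race lands in the physiological range and audits cleanly", {
  truth <- full_race()
  expect_equal(max(truth$lap), 3)
  active <- mean(truth$P_prop[!truth$tuck])
  expect_gt(active, 3)
  expect_lt(active, 5.5)
  expect_gt(mean(truth$tuck), 0.05)
  # per-lap energy closure within 0.1%
  audit <- energy_audit(truth, 77.1)
  expect_true(all(abs(audit$rel_error) < 1e-3))
  # tuck entered above 9 m/s, exited below 8 m/s (hysteresis)
  enters <- which(diff(truth$tuck) == 1)
  exits <- which(diff(truth$tuck) == -1)
  expect_true(all(truth$speed[enters + 1] > 9))
  expect_true(all(truth$speed[exits + 1] < 8 + 0.05))
})

test_that("halving the integration step leaves the trajectory unchanged (RK4 convergence)", {
  course <- small_course()
  ath <- athlete_model(); pol <- power_policy(); env <- default_env()
  par <- drag_model_params()
  t1 <- simulate_race(course, ath, pol, env, par, dt = 0.1, laps = 1)
  t2 <- simulate_race(course, ath, pol, env, par, dt = 0.05, laps = 1)
  v2 <- approx(t2$time, t2$speed, xout = t1$time, rule = 2)$y
  # tuck switching is quantized at dt (timing shifts of up to 0.1 s move
  # the speed by ~P/v * dt ~ 0.03 m/s near transitions), so compare in RMS
  # with a tolerance above that quantization floor
  expect_lt(sqrt(mean((t1$speed - v2)^2, na.rm = TRUE)), 0.01)
})

test_that("zero-noise sensors reproduce the truth exactly and seeds are reproducible", {
  sens <- small_sensors()
  truth <- small_race()
  gi <- seq(1, nrow(truth), by = 1)  # dt = 0.1 -> already 10 Hz
  expect_identical(sens$gnss$x, truth$x[gi])
  expect_identical(sens$gnss$z, truth$z[gi])
  # same seed twice: bit-identical noisy streams
  n1 <- synthesize_sensors(small_race(), small_course(),
                           sensor_noise_spec(seed = 99))
  n2 <- synthesize_sensors(small_race(), small_course(),
                           sensor_noise_spec(seed = 99))
  expect_identical(n1$gnss$x, n2$gnss$x)
  expect_identical(n1$imu_torso$gyro, n2$imu_torso$gyro)
  n3 <- synthesize_sensors(small_race(), small_course(),
                           sensor_noise_spec(seed = 100))
  expect_false(identical(n1$gnss$x, n3$gnss$x))
})

test_that("synthetic gyro levels separate active propulsion from the tuck", {
  sens <- small_sensors()
  truth <- small_race()
  tuck_t <- truth_at(truth, "tuck", sens$imu_torso$time) > 0.5
  # margin around transitions where the envelope is deliberately quiet
  g <- sens$imu_torso$gyro
  rms_axis <- sqrt(mean(g[!tuck_t, 1]^2))
  expect_gt(rms_axis, 150)  # spec: active rotation is vigorous
  in_tuck <- tuck_t & c(abs(diff(tuck_t)) == 0, TRUE)
  expect_lt(sqrt(mean(g[in_tuck, 1]^2)), 20)
})

test_that("dropping the reference trajectory degrades vertical accuracy", {
  # with default GNSS noise the standalone-vertical pathway deviates far
  # more from the truth than the reference-mapped pathway
  truth <- small_race()
  noisy <- synthesize_sensors(truth, small_course(),
                              sensor_noise_spec(seed = 13))
  ref_kin <- build_kinematics(lowpass_positions(noisy$gnss), noisy$reference)
  solo_kin <- build_kinematics(lowpass_positions(noisy$gnss), NULL)
  zt <- truth_at(truth, "z", ref_kin$time)
  err_ref <- sqrt(mean((ref_kin$z - zt)^2))
  err_solo <- sqrt(mean((solo_kin$z - zt)^2))
  expect_lt(err_ref, 0.2)
  expect_gt(err_solo, 2 * err_ref)
})
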