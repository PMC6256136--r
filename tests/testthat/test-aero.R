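# Aerodynamic model: atmosphere, wind profile, frontal areas, drag
# coefficient, drag force.

test_that("air density follows the ideal gas law", {
  # mid-race conditions: 96.6 kPa, 12.5 C
  expect_equal(air_density(96600, 285.65), 96600 / (287.058 * 285.65),
               tolerance = 1e-12)
  expect_equal(round(air_density(96600, 285.65), 3), 1.178)
  # standard atmosphere check
  expect_equal(air_density(101325, 288.15), 1.225, tolerance = 1e-3)
  # linear in pressure
  expect_equal(air_density(2 * 96600, 285.65), 2 * air_density(96600, 285.65))
  expect_error(air_density(-1, 280), "positive")
})

test_that("Sutherland viscosity hits its reference point and increases with T", {
  expect_equal(dynamic_viscosity(273.15), 1.716e-5, tolerance = 1e-12)
  # direct evaluation at 12.5 C
  mu_oracle <- 1.716e-5 * (273.15 + 110.4) / (285.65 + 110.4) *
    (285.65 / 273.15)^1.5
  expect_equal(dynamic_viscosity(285.65), mu_oracle, tolerance = 1e-15)
  expect_equal(dynamic_viscosity(285.65), 1.777e-5, tolerance = 1e-3)
  Ts <- seq(230, 330, 5)
  expect_true(all(diff(dynamic_viscosity(Ts)) > 0))
  expect_warning(dynamic_viscosity(200), "range")
})

test_that("Reynolds numbers span the skiing range 4e4 to 5e5", {
  # nu = mu / rho = 1.5e-5 m^2/s, L = 0.30 m
  rho <- 1.2; mu <- 1.5e-5 * rho
  expect_equal(reynolds(2, 0.30, rho, mu), 4e4, tolerance = 1e-12)
  expect_equal(reynolds(25, 0.30, rho, mu), 5e5, tolerance = 1e-12)
  expect_equal(reynolds(10, 0.30, rho, mu), 2 * reynolds(5, 0.30, rho, mu))
})

test_that("log wind profile halves 10 m wind at 1 m with z0 = 0.1", {
  expect_equal(wind_at_height(1, 1, 0.1), 0.5, tolerance = 1e-12)
  expect_equal(wind_at_height(7.3, 10, 0.1), 7.3)
  # strongest recorded hourly wind
  expect_equal(wind_at_height(4.48, 1, 0.1), 2.24, tolerance = 1e-12)
  expect_error(wind_at_height(5, 0.05, 0.1), "z > z0")
})

test_that("meteorological wind direction converts to a flow vector", {
  # northerly wind (from 0 deg) blows toward the south
  expect_equal(wind_vector(3, 0), c(0, -3, 0), tolerance = 1e-12)
  # westerly wind (from 270) blows toward the east
  expect_equal(wind_vector(2, 270), c(2, 0, 0), tolerance = 1e-12)
})

test_that("posture frontal area matches the regression model and its bounds", {
  p <- drag_model_params()
  # upright: A = 0.55 * 0.97 + 0.045
  expect_equal(frontal_area_imu(0, 0, p), 0.5785, tolerance = 1e-12)
  # fully pitched: cosines vanish
  expect_equal(frontal_area_imu(pi / 2, pi / 2, p), 0.55 * 0.27 + 0.045,
               tolerance = 1e-12)
  # monotone decreasing in each angle on [0, pi/2]
  th <- seq(0, pi / 2, length.out = 30)
  expect_true(all(diff(frontal_area_imu(th, 0.3, p)) < 0))
  expect_true(all(diff(frontal_area_imu(0.3, th, p)) < 0))
  # stays within [A_equip, 0.97 A0 + A_equip] over the whole posture square
  grid <- expand.grid(t1 = th, t2 = th)
  A <- frontal_area_imu(grid$t1, grid$t2, p)
  expect_true(all(A >= p$A_equip - 1e-12))
  expect_true(all(A <= 0.97 * p$A0 + p$A_equip + 1e-12))
})

test_that("allometric frontal area has the published plateaus and is non-increasing", {
  p <- drag_model_params()
  m <- 77.1
  expect_equal(frontal_area_allometric(0, m, p), 0.0289 * m^(2 / 3),
               tolerance = 1e-3)
  expect_equal(frontal_area_allometric(0, m, p), 0.525, tolerance = 0.005)
  expect_equal(frontal_area_allometric(100, m, p),
               (0.0289 - 0.0094) * m^(2 / 3), tolerance = 1e-3)
  expect_equal(frontal_area_allometric(100, m, p), 0.354, tolerance = 0.005)
  v <- seq(0, 20, 0.25)
  expect_true(all(diff(frontal_area_allometric(v, m, p)) <= 1e-12))
  # calibrated transition midpoint sits at the observed tuck speed
  Amid <- frontal_area_allometric(p$area_mid, m, p)
  expect_equal(Amid, (0.0289 - 0.0094 / 2) * m^(2 / 3), tolerance = 1e-6)
  # literal mode evaluates the printed exponent (transition near 16 m/s)
  plit <- drag_model_params(mode = "literal")
  Alit <- frontal_area_allometric(12.2 / 0.76, m, plit)
  expect_equal(Alit, (0.0289 - 0.0094 / 2) * m^(2 / 3), tolerance = 1e-6)
})

test_that("drag coefficient is anchored, rescaled, and non-increasing in Re", {
  p <- drag_model_params()
  expect_equal(drag_coefficient(p$re_schenau, p), 0.872, tolerance = 1e-12)
  Re <- seq(4e4, 5e5, length.out = 200)
  cd <- drag_coefficient(Re, p)
  expect_true(all(diff(cd) <= 1e-12))
  expect_true(all(is.finite(cd)))
  # low-Re / high-Re plateau ratio = alpha0 / (alpha0 - alpha1) ~ 2.26
  p2 <- drag_model_params(cd_mid = 2e5, cd_width = 1e4)  # sharp, in-range
  lo <- drag_coefficient(4e4, p2)
  hi <- drag_coefficient(5e5, p2)
  expect_equal(lo / hi, 1.29 / (1.29 - 0.72), tolerance = 0.01)
  # scaling property: C_D(Re) / C'_D-shape is a constant
  expect_warning(drag_coefficient(1e3, p), "clamped")
})

test_that("drag force is quadratic, antiparallel to relative flow, and dissipative", {
  v <- c(6, 0, 0)
  Fd <- drag_force(v, c(0, 0, 0), rho = 1.178, ACD = 0.5)
  expect_equal(sqrt(sum(Fd^2)), 0.5 * 1.178 * 36 * 0.5, tolerance = 1e-12)
  expect_equal(sum(Fd * v), -63.6, tolerance = 0.01)  # drag power, W
  expect_equal(as.numeric(Fd / sqrt(sum(Fd^2))), c(-1, 0, 0), tolerance = 1e-12)
  # moving with the air: no drag
  expect_equal(as.numeric(drag_force(v, v, 1.2, 0.5)), c(0, 0, 0))
  # headwind doubling relative speed quadruples the force
  F1 <- drag_force(c(3, 0, 0), c(0, 0, 0), 1.2, 0.5)
  F2 <- drag_force(c(3, 0, 0), c(-3, 0, 0), 1.2, 0.5)
  expect_equal(sqrt(sum(F2^2)) / sqrt(sum(F1^2)), 4, tolerance = 1e-12)
  # drag power never positive for any wind-free velocity
  set.seed(5)
  V <- matrix(rnorm(300), ncol = 3) * 5
  Fd_all <- drag_force(V, c(0, 0, 0), 1.2, 0.5)
  expect_true(all(rowSums(Fd_all * V) <= 0))
})

test_that("composite drag area at fixed posture is non-increasing with speed", {
  p <- drag_model_params()
  atm <- atmosphere(12.5, 96.6)
  v <- seq(2, 12, 0.1)
  Re <- reynolds(v, 0.30, atm$rho, atm$mu)
  A <- frontal_area_imu(0.35, 0.60, p)
  # at 2 m/s the Reynolds number sits a hair below the fitted range, so
  # the bottom edge is clamped (warning expected)
  acd <- A * suppressWarnings(drag_coefficient(Re, p))
  expect_true(all(diff(acd) <= 1e-12))
})

test_that("a 0.1 degree incline at 3 m/s maps to ~0.25 m^2 of apparent drag area", {
  atm <- atmosphere(12.5, 96.6)
  err <- drag_area_equivalent(0.1 * pi / 180, 3, 77.1, atm$rho)
  expect_equal(err, 0.25, tolerance = 0.02)
})
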