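# Trajectory processing: geodetic conversion, resampling, smoothing
# splines, low-pass filtering, map matching, derivatives, curvature.

test_that("ENU conversion maps the origin to zero and preserves geodesic distances", {
  org <- c(59.96, 10.66, 350)  # hilly terrain north of Oslo
  enu <- to_local_frame(org[1], org[2], org[3])
  expect_equal(as.numeric(enu), c(0, 0, 0), tolerance = 1e-12)

  # one arc-second north of the equator vs the full geodesic computation
  enu2 <- to_local_frame(c(0, 1 / 3600), c(0, 0), c(0, 0))
  d_geo <- geosphere::distGeo(c(0, 0), c(0, 1 / 3600))
  expect_equal(unname(enu2[2, 2]), d_geo, tolerance = 1e-6)
  expect_lt(abs(enu2[2, 1]), 1e-9)

  # distances over a ~10 km extent match the ellipsoid to < 0.01 %
  lat <- org[1] + c(0, 0.05); lon <- org[2] + c(0, 0.05)
  enu3 <- to_local_frame(lat, lon, c(350, 350))
  d_chord <- sqrt(sum((enu3[2, ] - enu3[1, ])^2))
  d_geo3 <- geosphere::distGeo(c(lon[1], lat[1]), c(lon[2], lat[2]))
  expect_lt(abs(d_chord - d_geo3) / d_geo3, 1e-4)
})

test_that("ENU conversion round-trips through geodetic to micrometer precision", {
  org <- c(59.96, 10.66, 350)
  set.seed(11)
  lat <- org[1] + runif(50, -0.05, 0.05)
  lon <- org[2] + runif(50, -0.05, 0.05)
  ele <- org[3] + runif(50, -60, 60)
  enu <- to_local_frame(lat, lon, ele, origin = org)
  back <- from_local_frame(enu, org)
  enu2 <- to_local_frame(back$lat_deg, back$lon_deg, back$ele_m, origin = org)
  expect_lt(max(abs(enu2 - enu)), 1e-6)
  expect_error(to_local_frame(91, 0, 0), "out-of-range")
})

test_that("reference resampling yields the requested spacing on lines and arcs", {
  straight <- data.frame(x = seq(0, 10, 0.5), y = 0, z = 0)
  rs <- resample_reference(straight, 1)
  expect_equal(nrow(rs), 11)
  expect_equal(rs$x, 0:10, tolerance = 1e-12)

  # idempotence on already-equidistant input
  rs2 <- resample_reference(rs, 1)
  expect_equal(rs2$x, rs$x, tolerance = 1e-9)

  # semicircle of radius 10 sampled at 0.1 m: arc length ~ pi * 10
  th <- seq(0, pi, length.out = 1000)
  semi <- data.frame(x = 10 * cos(th), y = 10 * sin(th), z = 0)
  rsc <- resample_reference(semi, 0.1)
  expect_equal(max(rsc$s), pi * 10, tolerance = pi * 10 * 0.005)

  expect_error(resample_reference(data.frame(x = c(1, 1, 1), y = 0, z = 0)),
               "degenerate")
})

test_that("penalized smoothing spline has the interpolation and straight-line limits", {
  set.seed(21)
  x <- seq(0, 100, 2)
  y_true <- 0.5 * x + 3
  # noiseless straight line stays on the line for any p
  for (p in c(1, 0.1, 1e-4)) {
    expect_lt(max(abs(penalized_spline(x, y_true, p = p) - y_true)), 1e-8)
  }
  y <- sin(x / 8) + rnorm(length(x), 0, 0.3)
  # p = 1 interpolates
  expect_lt(max(abs(penalized_spline(x, y, p = 1) - y)), 1e-9)
  # p -> 0 approaches the weighted least-squares line
  fit0 <- penalized_spline(x, y, p = 1e-12)
  ls <- unname(stats::lm(y ~ x)$fitted.values)
  expect_equal(fit0, ls, tolerance = 1e-4)
  expect_error(penalized_spline(x, y, w = rep(-1, length(x))), "positive")
})

test_that("spline smoothing at p = 0.02 reduces noise on a sinusoidal track", {
  set.seed(22)
  s <- seq(0, 500)
  z_true <- 5 * sin(2 * pi * s / 180)
  z_noisy <- z_true + rnorm(length(s), 0, 0.05)
  fit <- penalized_spline(s, z_noisy, p = 0.02)
  rms_in <- sqrt(mean((z_noisy - z_true)^2))
  rms_out <- sqrt(mean((fit - z_true)^2))
  expect_lt(rms_out, rms_in)
})

test_that("fix-quality weighting pulls the smoothed track toward fixed points", {
  set.seed(23)
  s <- seq(0, 300)
  fq <- rep("fixed", length(s))
  fq[100:140] <- "float"
  noise <- ifelse(fq == "float", 0.8, 0.03)
  tr <- reference_track(s, s + rnorm(length(s), 0, noise) * 0,
                        rnorm(length(s), 0, noise),
                        2 + rnorm(length(s), 0, noise), fix_quality = fq)
  sm <- smooth_reference(tr, p = 0.02)
  res_fixed <- abs(sm$z[sm$fix_quality == "fixed"] - 2)
  res_float <- abs(sm$z[sm$fix_quality == "float"] - 2)
  # smoothed curve ignores the noisy float excursions
  expect_lt(mean(res_fixed), 0.05)
  expect_lt(mean(res_float), 0.4)
})

test_that("bidirectional Butterworth filter is zero-phase with the squared magnitude response", {
  fs <- 10
  tm <- seq(0, 200, 1 / fs)
  const <- geo_trajectory(tm, rep(5, length(tm)), rep(-2, length(tm)),
                          rep(1, length(tm)))
  expect_equal(lowpass_positions(const)$x, const$x, tolerance = 1e-9)

  # analytic oracle: |H|^2 of a second-order Butterworth at f/fc
  bw2 <- function(f, fc) 1 / (1 + (f / fc)^4)  # squared magnitude, order 2
  gains <- sapply(c(0.05, 3), function(f) {
    traj <- geo_trajectory(tm, sin(2 * pi * f * tm), rep(0, length(tm)),
                           rep(0, length(tm)))
    filt <- lowpass_positions(traj, cutoff_hz = 0.3)
    max(abs(filt$x[tm > 50 & tm < 150]))
  })
  expect_equal(gains[1], bw2(0.05, 0.3), tolerance = 1e-3)
  expect_gt(gains[1], 0.99)           # passband: < 1% attenuation
  expect_equal(gains[2], bw2(3, 0.3), tolerance = 1e-4)
  expect_lt(gains[2], 1e-3)           # stopband: > 99.9% attenuation
  expect_error(lowpass_positions(const, cutoff_hz = 6), "Nyquist")
})

test_that("map matching equals exhaustive nearest-point search", {
  set.seed(31)
  course <- small_course()
  # brute-force oracle: nearest vertex over all reference points, then the
  # same local segment refinement
  brute <- function(q) {
    d2 <- (course$x - q[1])^2 + (course$y - q[2])^2
    i <- order(d2, course$s)[1]
    list(s_vertex = course$s[i])
  }
  for (k in 1:1000) {
    i <- sample(nrow(course), 1)
    q <- c(course$x[i] + runif(1, -3, 3), course$y[i] + runif(1, -3, 3))
    m <- map_to_reference(q, course)
    b <- brute(q)
    # the refined match lies within one grid spacing of the brute vertex
    # (modulo the lap closure)
    dd <- abs(m$s - b$s_vertex)
    lap <- attr(course, "lap_length")
    expect_lt(min(dd, lap - dd), 1.0 + 1e-9)
    expect_true(m$mapped)
  }
  # query exactly on a reference point returns that point
  m <- map_to_reference(c(course$x[50], course$y[50]), course)
  expect_equal(m$s, course$s[50], tolerance = 1e-9)
  expect_equal(m$z, course$z[50], tolerance = 1e-9)
  # beyond the gate the sample is flagged unmapped
  far <- map_to_reference(c(max(course$x) + 100, 0), course, gate = 20)
  expect_false(far$mapped)
})

test_that("map matching breaks ties toward the smaller arc length", {
  ref <- reference_track(0:10, 0:10, rep(0, 11), rep(0, 11))
  m <- map_to_reference(c(5, 0), ref)
  expect_equal(m$s, 5)  # on-segment projection
  # U-shaped track: outbound branch along y = 0 (s = 0..10), return branch
  # along y = 2 (s ~ 12..22); a query on the symmetry line is equidistant
  # from both branches and must match the outbound (smaller s) one
  xs <- c(0:10, 10, 10:0)
  ys <- c(rep(0, 11), 1, rep(2, 11))
  seg <- cumsum(c(0, sqrt(diff(xs)^2 + diff(ys)^2)))
  refu <- reference_track(seg, xs, ys, rep(0, length(xs)))
  m2 <- map_to_reference(c(5, 1), refu)
  expect_lte(m2$s, 10)
})

test_that("five-point finite differences are exact on quartics", {
  tm <- 0:10
  expect_equal(finite_difference(rep(3, 11), 1), rep(0, 11), tolerance = 1e-12)
  d <- finite_difference(tm^4, 1)
  expect_equal(d, 4 * tm^3, tolerance = 1e-8)
  # all five-point stencils (edges included) are exact for degree <= 4
  for (k in 0:4) {
    expect_equal(finite_difference(tm^k, 1), k * tm^pmax(k - 1, 0),
                 tolerance = 1e-8)
  }
  tm2 <- seq(0, 2 * pi, 0.01)
  err <- finite_difference(sin(tm2), 0.01) - cos(tm2)
  expect_lt(max(abs(err)), 1e-8)
  expect_error(finite_difference(1:4, 1), "at least 5")
})

test_that("curvature is 1/r on circles, zero on lines, and scale-invariant", {
  for (r in c(5, 25, 100)) {
    v <- c(8, 0, 0)
    a <- c(0, 8^2 / r, 0)  # centripetal
    K <- curvature(v, a)
    expect_equal(sqrt(sum(K^2)), 1 / r, tolerance = 1e-12)
    expect_equal(sum(K * v), 0, tolerance = 1e-12)
    # K points toward the center (same direction as a)
    expect_gt(sum(K * a), 0)
  }
  expect_equal(as.numeric(curvature(c(5, 0, 0), c(2, 0, 0))), c(0, 0, 0))
  # lambda-scaling of v and lambda^2 of a leaves K unchanged
  K1 <- curvature(c(3, 4, 0), c(-1, 2, 0.5))
  K2 <- curvature(3 * c(3, 4, 0), 9 * c(-1, 2, 0.5))
  expect_equal(as.numeric(K1), as.numeric(K2), tolerance = 1e-12)
  # below the speed floor: zero and flagged
  K3 <- curvature(c(0.1, 0, 0), c(0, 1, 0))
  expect_equal(as.numeric(K3), c(0, 0, 0))
  expect_equal(attr(K3, "flagged"), 1L)
})

test_that("kinematics of uniform motion on a straight flat course are exact", {
  ana <- flat_scenario(speed = 5, duration = 100)
  kin <- ana$kinematics
  int <- 11:(nrow(kin) - 10)
  expect_lt(max(abs(kin$speed[int] - 5)), 1e-6)
  expect_lt(max(abs(kin$accel_along[int])), 1e-6)
  expect_lt(max(abs(kin$incline[int])), 1e-6)
})

test_that("constant-speed travel on a 5% grade recovers the analytic vertical velocity", {
  grade <- 0.05
  sp <- 6  # 3D speed
  tm <- seq(0, 120, 0.1)
  vh <- sp / sqrt(1 + grade^2)
  gnss <- geo_trajectory(tm, vh * tm, rep(0, length(tm)), vh * grade * tm)
  smax <- 800
  sgrid <- seq(0, smax)
  hx <- sgrid / sqrt(1 + grade^2)
  ref <- reference_track(sgrid, hx, rep(0, smax + 1), hx * grade)
  kin <- build_kinematics(lowpass_positions(gnss), ref)
  int <- 11:(nrow(kin) - 10)
  vz_expected <- grade / sqrt(1 + grade^2) * sp
  expect_equal(mean(kin$vz[int]), vz_expected, tolerance = 1e-3)
  expect_equal(mean(kin$incline[int]), atan(grade), tolerance = 1e-3)
})

test_that("repeated low-pass filtering is nearly idempotent", {
  # a second pass changes the signal RMS by < 1% of the first pass's
  # RMS change: the passband is flat, so refiltering an already
  # band-limited signal has almost no effect on its energy
  set.seed(41)
  tm <- seq(0, 300, 0.1)
  x <- 10 * sin(2 * pi * tm / 60) + rnorm(length(tm), 0, 1)
  traj <- geo_trajectory(tm, x, rep(0, length(tm)), rep(0, length(tm)))
  f1 <- lowpass_positions(traj)
  f2 <- lowpass_positions(f1)
  rms <- function(v) sqrt(mean(v^2))
  change1 <- abs(rms(f1$x) - rms(traj$x))
  change2 <- abs(rms(f2$x) - rms(f1$x))
  expect_lt(change2, 0.01 * change1)
})

test_that("noise-free simulator kinematics are recovered to the stated tolerances", {
  kin <- full_analysis()$kinematics
  truth <- full_race()
  int <- 11:(nrow(kin) - 10)
  v_err <- kin$speed[int] - truth_at(truth, "speed", kin$time[int])
  a_err <- kin$accel_along[int] - truth_at(truth, "accel", kin$time[int])
  expect_lt(sqrt(mean(v_err^2)), 0.01)
  expect_lt(sqrt(mean(a_err^2)), 0.05)
})
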