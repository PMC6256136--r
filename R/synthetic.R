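# Forward-dynamics race generator: undulating closed course, point-mass
# skier driven by a speed/acceleration power policy with a tuck rule, and
# synthesis of noisy GNSS / IMU sensor streams from the simulated truth.

#' Course specification for the synthetic generator
#'
#' Defaults emulate a World-Cup-like roller-ski course: 4.5 km laps,
#' 51 m height difference and 166 m total climb per lap, skied three times.
#'
#' @param lap_length lap length (m).
#' @param laps number of laps.
#' @param height_diff difference between highest and lowest point (m).
#' @param total_climb sum of ascent per lap (m); must be >= `height_diff`.
#' @param n_float number of short degraded-survey ("float") sections.
#' @param float_length length of each float section (m).
#' @param seed seed for the float-section placement.
#' @return list of class `course_spec`.
#' @export
course_spec <- function(lap_length = 4500, laps = 3, height_diff = 51,
                        total_climb = 166, n_float = 5, float_length = 30,
                        seed = 1) {
  if (total_climb < height_diff) stop("infeasible course: total climb < height difference")
  structure(list(lap_length = lap_length, laps = laps,
                 height_diff = height_diff, total_climb = total_climb,
                 n_float = n_float, float_length = float_length, seed = seed),
            class = "course_spec")
}

# elevation shape: slow main undulation plus faster harmonics whose mix q
# controls the climb-to-range ratio
course_z_shape <- function(s, L, q) {
  th <- 2 * pi * s / L
  sin(th + 0.3) + q * (0.45 * sin(4 * th + 1.3) + 0.35 * sin(7 * th + 2.1) +
                         0.25 * sin(11 * th + 0.5))
}

#' Generate a synthetic closed-loop course
#'
#' Horizontal layout is a smoothly perturbed loop scaled to the requested
#' lap length; the elevation profile mixes a slow undulation with faster
#' harmonics, with the mix solved (by root finding at build time) so the
#' realized height difference and total climb match the spec within 2%.
#' A few short sections are flagged `float` to emulate degraded
#' carrier-phase survey quality.
#'
#' @param spec a [course_spec()].
#' @param spacing arc-length spacing of the returned track (m).
#' @return a closed [reference_track()] with the spec in attribute `spec`.
#' @export
generate_course <- function(spec, spacing = 1.0) {
  L <- spec$lap_length
  # horizontal shape: perturbed circle, scaled to perimeter L
  nphi <- 8192
  phi <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
  r <- 1 + 0.12 * sin(2 * phi + 0.7) + 0.07 * cos(3 * phi)
  xs <- r * cos(phi); ys <- r * sin(phi)
  per <- sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  sc <- L / per
  xs <- xs * sc; ys <- ys * sc
  sh <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  # elevation: solve the harmonic mix for the climb/range ratio, then scale
  sfine <- seq(0, L, length.out = 4096)
  if (spec$total_climb == 0 || spec$height_diff == 0) {
    zs <- rep(0, length(xs))
  } else {
    target_ratio <- spec$total_climb / spec$height_diff
    ratio_of <- function(q) {
      zz <- course_z_shape(sfine, L, q)
      climb <- sum(pmax(diff(zz), 0))
      climb / diff(range(zz))
    }
    q <- stats::uniroot(function(q) ratio_of(q) - target_ratio,
                        lower = 0.001, upper = 6, tol = 1e-10)$root
    zz <- course_z_shape(sfine, L, q)
    amp <- spec$height_diff / diff(range(zz))
    zs <- amp * course_z_shape(sh, L, q)
  }
  fq <- rep("fixed", length(xs))
  if (spec$n_float > 0) {
    starts <- with_seed(spec$seed,
                        sort(stats::runif(spec$n_float, 0, L - spec$float_length)))
    for (s0 in starts) fq[sh >= s0 & sh <= s0 + spec$float_length] <- "float"
  }
  track <- resample_reference(
    data.frame(x = xs, y = ys, z = zs, fix_quality = fq),
    spacing = spacing, closed = TRUE)
  attr(track, "spec") <- spec
  track
}

# Smooth course geometry (position, tangent, grade, curvature) as C2 cubic
# splines of arc length: periodic splines on closed loops, natural splines
# otherwise. Analytic spline derivatives keep the gravity term exactly
# consistent with the elevation profile, so the forward integrator
# conserves energy to RK4 accuracy.
course_geometry <- function(course) {
  Lp <- attr(course, "lap_length") %||%
    (max(course$s) + stats::median(diff(course$s)))
  xyz <- as.matrix(course[, c("x", "y", "z")])
  n <- nrow(xyz)
  ds <- stats::median(diff(course$s))
  truly_closed <- isTRUE(attr(course, "closed")) &&
    sqrt(sum((xyz[1, ] - xyz[n, ])^2)) < 5 * ds
  if (truly_closed) {
    sp <- lapply(1:3, function(k) {
      stats::splinefun(c(course$s, Lp), c(xyz[, k], xyz[1, k]),
                       method = "periodic")
    })
    wrap <- function(s) s %% Lp
  } else {
    sp <- lapply(1:3, function(k) {
      stats::splinefun(course$s, xyz[, k], method = "natural")
    })
    wrap <- function(s) pmin(pmax(s, min(course$s)), max(course$s))
  }
  list(
    lap_length = Lp,
    at = function(s) {
      sm <- wrap(s)
      d1 <- cbind(sp[[1]](sm, deriv = 1), sp[[2]](sm, deriv = 1),
                  sp[[3]](sm, deriv = 1))
      d2 <- cbind(sp[[1]](sm, deriv = 2), sp[[2]](sm, deriv = 2),
                  sp[[3]](sm, deriv = 2))
      nrm <- row_norm(d1)
      tg <- d1 / nrm
      kap <- (d2 - tg * rowSums(d2 * tg)) / nrm^2
      st <- pmin(pmax(d1[, 3] / nrm, -0.99), 0.99)
      list(pos = cbind(sp[[1]](sm), sp[[2]](sm), sp[[3]](sm)),
           tangent = tg,
           sin_theta = st, cos_theta = sqrt(pmax(1 - st^2, 0)),
           kappa = kap)
    })
}

#' Posture schedule used by the simulator
#'
#' Maps the dynamic state to torso and thigh pitch angles: a fixed moderate
#' lean during active propulsion (increasing slightly with grade) and a
#' deep crouch in the tuck. Any monotone, consistent mapping suffices for
#' exercising the posture-dependent area model; this one is piecewise
#' linear with documented constants.
#'
#' @param tuck logical tuck state.
#' @param grade course grade (rise over run), vectorized.
#' @return list with `theta_torso`, `theta_thigh` (rad).
#' @export
posture_schedule <- function(tuck, grade = 0) {
  lean <- 0.35 + 0.5 * pmin(pmax(grade, 0), 0.12)
  list(theta_torso = ifelse(tuck, 1.13, lean),
       theta_thigh = ifelse(tuck, 1.31, 0.60))
}

#' Simulate a race with forward dynamics
#'
#' Integrates the point-mass along-track equation of motion
#' `m dv/dt = P/v - m g (sin th + Crr cos th_eff) - drag` with a 4th-order
#' Runge-Kutta scheme at `dt`, where the commanded power follows the
#' policy `P(v, vdot)` (solved self-consistently for the vdot coupling),
#' clamped to the policy floor/ceiling and zeroed in the tuck. The drag
#' area follows the [posture_schedule()] through the same frontal-area and
#' drag-coefficient models the processing pipeline uses, and rolling
#' resistance includes the centripetal load of the course's turns.
#'
#' @param course a closed [reference_track()] from [generate_course()].
#' @param athlete an [athlete_model()].
#' @param policy a [power_policy()].
#' @param env an [environment_record()].
#' @param params a [drag_model_params()].
#' @param dt integration step (s), <= 0.1.
#' @param v0 initial speed (m/s).
#' @param laps number of laps (defaults to the course spec).
#' @return data frame of class `race_truth` with per-step time, arc
#'   position, position, speed, acceleration, commanded power (W/kg),
#'   component powers, tuck state and scheduled pitch angles.
#' @export
simulate_race <- function(course, athlete, policy, env, params,
                          dt = 0.1, v0 = 3,
                          laps = attr(course, "spec")$laps %||% 3) {
  stopifnot(dt <= 0.1 + 1e-12)
  geom <- course_geometry(course)
  Lp <- geom$lap_length
  total_dist <- laps * Lp
  atm <- atmosphere(env$temp_C, env$pressure_kPa)
  wind <- wind_vector(wind_at_height(env$wind10m_ms, env$wind_height_m, env$z0),
                      env$wind_dir_deg)
  m <- athlete$mass_kg
  a_v <- policy$slope_v; b_vd <- policy$slope_vdot; c0 <- policy$intercept

  # along-track derivative and commanded power at state (s, v, tuck)
  deriv <- function(s, v, tuck) {
    g <- geom$at(s)
    tg <- as.numeric(g$tangent)
    post <- posture_schedule(tuck, g$sin_theta / max(g$cos_theta, 1e-9))
    A <- frontal_area_imu(post$theta_torso, post$theta_thigh, params)
    vel <- v * tg
    vf <- vel - wind
    spf <- sqrt(sum(vf^2))
    Re <- reynolds(max(spf, 0.1), params$L, atm$rho, atm$mu)
    cd <- suppressWarnings(drag_coefficient(Re, params))
    drag_pm <- -0.5 * atm$rho * A * cd * spf * sum(vf * tg) / m
    Ng <- m * G_ACCEL * g$cos_theta
    n_hat <- c(-tg[1] * tg[3], -tg[2] * tg[3], 1 - tg[3]^2)
    n_hat <- n_hat / max(sqrt(sum(n_hat^2)), 1e-12)
    Fc <- m * v^2 * as.numeric(g$kappa)
    roll_pm <- athlete$crr * sqrt(sum((Ng * n_hat + Fc)^2)) / m
    D <- -G_ACCEL * g$sin_theta + drag_pm - roll_pm
    if (tuck) {
      P <- 0
      vdot <- D
    } else {
      vdot <- (a_v + c0 / v + D) / (1 - b_vd / v)
      P <- a_v * v + b_vd * vdot + c0
      if (P < policy$floor || P > policy$ceiling) {
        P <- min(max(P, policy$floor), policy$ceiling)
        vdot <- P / v + D
      }
    }
    list(vdot = vdot, sdot = v, P = P,
         drag_power = drag_pm * v, roll_power = -roll_pm * v,
         grade = g$sin_theta / max(g$cos_theta, 1e-9))
  }

  nmax <- ceiling(total_dist / 1.0 / dt) + 10000L
  tt <- ss <- vv <- aa <- PP <- dragP <- rollP <- numeric(nmax)
  tk <- logical(nmax)
  i <- 1L
  s <- 0; v <- v0; tuck <- FALSE
  repeat {
    d1 <- deriv(s, v, tuck)
    if (i > nmax) stop("simulation exceeded the step budget")
    tt[i] <- (i - 1L) * dt; ss[i] <- s; vv[i] <- v; aa[i] <- d1$vdot
    PP[i] <- d1$P; dragP[i] <- d1$drag_power; rollP[i] <- d1$roll_power
    tk[i] <- tuck
    if (s >= total_dist) break
    d2 <- deriv(s + dt / 2 * d1$sdot, v + dt / 2 * d1$vdot, tuck)
    d3 <- deriv(s + dt / 2 * d2$sdot, v + dt / 2 * d2$vdot, tuck)
    d4 <- deriv(s + dt * d3$sdot, v + dt * d3$vdot, tuck)
    s <- s + dt / 6 * (d1$sdot + 2 * d2$sdot + 2 * d3$sdot + d4$sdot)
    v <- v + dt / 6 * (d1$vdot + 2 * d2$vdot + 2 * d3$vdot + d4$vdot)
    if (v < 0.3) {
      stop("speed collapsed on a climb under this policy; increase the intercept")
    }
    tuck <- if (tuck) v > policy$tuck_exit else v > policy$tuck_enter
    i <- i + 1L
  }
  idx <- seq_len(i)
  g <- geom$at(ss[idx])
  post <- posture_schedule(tk[idx], g$sin_theta / pmax(g$cos_theta, 1e-9))
  out <- data.frame(time = tt[idx], s_total = ss[idx], s = ss[idx] %% Lp,
                    lap = pmin(floor(ss[idx] / Lp) + 1L, laps),
                    x = g$pos[, 1], y = g$pos[, 2], z = g$pos[, 3],
                    speed = vv[idx], accel = aa[idx], P_prop = PP[idx],
                    P_drag = dragP[idx], P_roll = rollP[idx],
                    grade = g$sin_theta / pmax(g$cos_theta, 1e-9),
                    tuck = tk[idx],
                    theta_torso = post$theta_torso,
                    theta_thigh = post$theta_thigh)
  attr(out, "dt") <- dt
  attr(out, "lap_length") <- Lp
  class(out) <- c("race_truth", "data.frame")
  out
}

#' Sensor-noise specification
#'
#' @param gnss_h_sd,gnss_v_sd horizontal/vertical GNSS noise SD (m).
#' @param ref_sd reference-track survey noise SD (m); float sections are
#'   inflated by `ref_float_factor`.
#' @param ref_float_factor noise inflation in float sections.
#' @param accel_sd accelerometer noise SD (g).
#' @param gyro_sd gyroscope noise SD (deg/s).
#' @param gyro_active_amp sinusoidal gyro amplitude per axis during active
#'   propulsion (deg/s).
#' @param gyro_freq_hz poling-cadence frequency of the synthetic gyro (Hz).
#' @param transition_lead_s quiet margin around tuck transitions (s): the
#'   athlete stops large segment rotations slightly before crouching and
#'   resumes slightly after rising, which also makes the smoothed-energy
#'   threshold crossing an approximately unbiased estimate of the boundary.
#' @param seed master noise seed.
#' @return list of class `sensor_noise_spec`.
#' @export
sensor_noise_spec <- function(gnss_h_sd = 1.0, gnss_v_sd = 2.0, ref_sd = 0.02,
                              ref_float_factor = 25, accel_sd = 0.02,
                              gyro_sd = 8, gyro_active_amp = 230,
                              gyro_freq_hz = 0.9, transition_lead_s = 1.3,
                              seed = 1) {
  stopifnot(gnss_h_sd >= 0, gnss_v_sd >= 0, ref_sd >= 0, accel_sd >= 0,
            gyro_sd >= 0)
  structure(list(gnss_h_sd = gnss_h_sd, gnss_v_sd = gnss_v_sd, ref_sd = ref_sd,
                 ref_float_factor = ref_float_factor, accel_sd = accel_sd,
                 gyro_sd = gyro_sd, gyro_active_amp = gyro_active_amp,
                 gyro_freq_hz = gyro_freq_hz,
                 transition_lead_s = transition_lead_s, seed = seed),
            class = "sensor_noise_spec")
}

#' Synthesize sensor streams from simulated truth
#'
#' Produces what the wearable sensors would have recorded: a 10 Hz GNSS
#' position stream (truth plus i.i.d. Gaussian noise), 100 Hz torso and
#' thigh IMU streams whose smoothed accelerometer pitch encodes the
#' scheduled posture and whose gyro energy encodes the tuck state, and a
#' surveyed reference track with inflated noise in the float sections.
#' With all noise SDs zero the GNSS equals the truth exactly. All noise is
#' drawn from per-stream substreams of `noise$seed`, so identical seeds
#' give bit-identical output.
#'
#' @param truth a `race_truth` from [simulate_race()].
#' @param course the course the truth was simulated on.
#' @param noise a [sensor_noise_spec()].
#' @param gnss_hz,imu_hz output rates.
#' @return list with `gnss` ([geo_trajectory()]), `imu_torso`, `imu_thigh`
#'   ([imu_stream()]) and `reference` ([reference_track()]).
#' @export
synthesize_sensors <- function(truth, course, noise = sensor_noise_spec(),
                               gnss_hz = 10, imu_hz = 100) {
  dt <- attr(truth, "dt")
  seeds <- derive_seeds(noise$seed, 4)
  # --- GNSS at gnss_hz ---
  step <- max(1L, round(1 / (gnss_hz * dt)))
  gi <- seq(1L, nrow(truth), by = step)
  gnss <- with_seed(seeds[1], geo_trajectory(
    time = truth$time[gi],
    x = truth$x[gi] + stats::rnorm(length(gi), 0, noise$gnss_h_sd),
    y = truth$y[gi] + stats::rnorm(length(gi), 0, noise$gnss_h_sd),
    z = truth$z[gi] + stats::rnorm(length(gi), 0, noise$gnss_v_sd),
    nominal_hz = gnss_hz))
  # --- IMU at imu_hz ---
  ti <- seq(0, max(truth$time), by = 1 / imu_hz)
  interp <- function(v) stats::approx(truth$time, v, xout = ti, rule = 2)$y
  tuck_t <- interp(as.numeric(truth$tuck)) > 0.5
  # quiet margin around tuck transitions for the gyro envelope
  lead_n <- round(noise$transition_lead_s * imu_hz)
  quiet <- tuck_t
  if (lead_n > 0 && any(tuck_t) && !all(tuck_t)) {
    edges <- which(diff(tuck_t) != 0)
    for (e in edges) {
      quiet[max(1, e - lead_n + 1):min(length(quiet), e + lead_n)] <- TRUE
    }
    quiet <- quiet | tuck_t
  }
  th_to <- interp(truth$theta_torso)
  th_th <- interp(truth$theta_thigh)
  make_imu <- function(theta, location, seed) {
    with_seed(seed, {
      n <- length(ti)
      amp <- ifelse(quiet, 0, noise$gyro_active_amp)
      # phase-staggered axes make |omega|^2 constant during activity
      gx <- amp * sin(2 * pi * noise$gyro_freq_hz * ti) +
        stats::rnorm(n, 0, noise$gyro_sd)
      gy <- amp * sin(2 * pi * noise$gyro_freq_hz * ti + 2 * pi / 3) +
        stats::rnorm(n, 0, noise$gyro_sd)
      gz <- amp * sin(2 * pi * noise$gyro_freq_hz * ti + 4 * pi / 3) +
        stats::rnorm(n, 0, noise$gyro_sd)
      ax <- stats::rnorm(n, 0, noise$accel_sd)
      ay <- sin(theta) + stats::rnorm(n, 0, noise$accel_sd)
      az <- cos(theta) + stats::rnorm(n, 0, noise$accel_sd)
      imu_stream(ti, cbind(ax, ay, az), cbind(gx, gy, gz),
                 location = location, accel_units = "g", gyro_units = "dps")
    })
  }
  imu_torso <- make_imu(th_to, "torso", seeds[2])
  imu_thigh <- make_imu(th_th, "thigh", seeds[3])
  # --- reference track: course survey with per-point noise ---
  ref <- with_seed(seeds[4], {
    sd_pt <- ifelse(course$fix_quality == "float",
                    noise$ref_sd * noise$ref_float_factor, noise$ref_sd)
    n <- nrow(course)
    reference_track(course$s,
                    course$x + stats::rnorm(n, 0, sd_pt),
                    course$y + stats::rnorm(n, 0, sd_pt),
                    course$z + stats::rnorm(n, 0, sd_pt),
                    fix_quality = course$fix_quality,
                    closed = isTRUE(attr(course, "closed")))
  })
  attr(ref, "lap_length") <- attr(course, "lap_length")
  list(gnss = gnss, imu_torso = imu_torso, imu_thigh = imu_thigh,
       reference = ref)
}

#' Per-lap energy audit of a simulated race
#'
#' Checks that the integral of commanded propulsive power over each lap
#' equals the change in mechanical energy plus the dissipated drag and
#' rolling energy (trapezoidal integration of the recorded series).
#'
#' @param truth a `race_truth`.
#' @param mass system mass (kg).
#' @return data frame per lap with `work_prop`, `delta_Emech`,
#'   `dissipated` (J/kg) and the relative closure error.
#' @export
energy_audit <- function(truth, mass) {
  trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  out <- do.call(rbind, lapply(split(seq_len(nrow(truth)), truth$lap), function(ix) {
    d <- truth[ix, ]
    wp <- trapz(d$time, d$P_prop)
    dE <- 0.5 * (d$speed[nrow(d)]^2 - d$speed[1]^2) +
      G_ACCEL * (d$z[nrow(d)] - d$z[1])
    diss <- -trapz(d$time, d$P_drag + d$P_roll)
    data.frame(lap = d$lap[1], work_prop = wp, delta_Emech = dE,
               dissipated = diss,
               rel_error = (wp - dE - diss) / max(abs(wp), 1))
  }))
  rownames(out) <- NULL
  out
}
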