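# End-to-end processing: sensors in, power series and race summary out.

#' Tuck flags from speed alone (sensor-free fallback)
#'
#' Hysteresis rule on speed used when no IMU streams are available: enter
#' the tuck above `enter`, leave below `exit`. Mirrors the observed
#' transition speed of ~9 m/s.
#'
#' @param speed speed series (m/s).
#' @param enter,exit hysteresis thresholds (m/s).
#' @return logical vector.
#' @export
tuck_from_speed <- function(speed, enter = 9, exit = 8) {
  tuck <- logical(length(speed))
  state <- FALSE
  for (i in seq_along(speed)) {
    state <- if (state) speed[i] > exit else speed[i] > enter
    tuck[i] <- state
  }
  tuck
}

# Drag and rolling power per kg on a kinematic series. Factored out so the
# Monte Carlo can re-evaluate it with perturbed parameters on fixed
# kinematics.
#   area: list(model = "imu"|"allometric", theta_torso, theta_thigh)
compute_resistive_powers <- function(kin, area, athlete, atm, wind_vec, params,
                                     crr = athlete$crr,
                                     cd_schenau = params$cd_schenau,
                                     area_offset = 0) {
  vel <- as.matrix(kin[, c("vx", "vy", "vz")])
  vf <- vel - matrix(wind_vec, nrow(kin), 3, byrow = TRUE)
  spf <- row_norm(vf)
  A <- if (area$model == "imu") {
    frontal_area_imu(area$theta_torso, area$theta_thigh, params,
                     A0 = athlete$A0_m2)
  } else {
    frontal_area_allometric(kin$speed, athlete$mass_kg, params)
  }
  A <- pmax(A + area_offset, params$A_equip)
  Re <- reynolds(pmax(spf, 0.1), athlete$L_m, atm$rho, atm$mu)
  cd <- suppressWarnings(drag_coefficient(Re, params, cd_schenau = cd_schenau))
  Fd <- drag_force(vel, wind_vec, atm$rho, A * cd)
  P_drag <- rowSums(Fd * vel) / athlete$mass_kg
  Ng <- normal_force(athlete$mass_kg, kin$incline)
  K <- as.matrix(kin[, c("curv_x", "curv_y", "curv_z")])
  Fc <- centripetal_force(athlete$mass_kg, vel, K)
  P_roll <- rolling_power(crr, Ng, Fc, vel) / athlete$mass_kg
  list(P_drag = P_drag, P_roll = P_roll, ACD = A * cd)
}

#' Process a full race from sensor streams to propulsive power
#'
#' Runs the complete pipeline: low-pass filtering of the GNSS stream, map
#' matching against the reference trajectory, 1 Hz kinematics, IMU posture
#' and tuck detection, posture-dependent (or allometric) drag area,
#' Reynolds-dependent drag coefficient, rolling resistance with
#' centripetal loading, and the power-balance inversion with 5 s smoothing
#' and tuck zeroing.
#'
#' @param gnss a [geo_trajectory()] (10 Hz athlete stream).
#' @param reference a [reference_track()] (pass the surveyed track after
#'   [smooth_reference()]), or `NULL` to use standalone GNSS height (the
#'   degraded pathway).
#' @param imu_torso,imu_thigh aligned [imu_stream()] objects, or `NULL`
#'   to fall back to [tuck_from_speed()] and the allometric area model.
#' @param athlete an [athlete_model()].
#' @param env an [environment_record()].
#' @param params a [drag_model_params()].
#' @param area_model `"imu"` or `"allometric"`.
#' @param smooth_window_s power smoothing window (s).
#' @param ... passed to [build_kinematics()].
#' @return list of class `race_analysis`: `kinematics`, `posture` (1 Hz),
#'   `power` (a `power_series`), `summary` (a `race_summary`), plus the
#'   model inputs used.
#' @export
process_race <- function(gnss, reference, imu_torso = NULL, imu_thigh = NULL,
                         athlete = athlete_model(), env = environment_record(),
                         params = drag_model_params(),
                         area_model = c("imu", "allometric"),
                         smooth_window_s = 5, ...) {
  area_model <- match.arg(area_model)
  have_imu <- !is.null(imu_torso) && !is.null(imu_thigh)
  if (area_model == "imu" && !have_imu) {
    stop("area_model = 'imu' requires both IMU streams; use 'allometric'")
  }
  traj <- lowpass_positions(gnss)
  kin <- build_kinematics(traj, reference, ...)
  if (have_imu) {
    post <- posture_series(imu_torso, imu_thigh)
    post1 <- aggregate_posture(post, kin$time)
    tuck <- post1$tuck
  } else {
    post1 <- NULL
    tuck <- tuck_from_speed(kin$speed)
  }
  atm <- atmosphere(env$temp_C, env$pressure_kPa)
  wvec <- wind_vector(wind_at_height(env$wind10m_ms, env$wind_height_m, env$z0),
                      env$wind_dir_deg)
  area <- if (area_model == "imu") {
    list(model = "imu", theta_torso = post1$theta_torso,
         theta_thigh = post1$theta_thigh)
  } else list(model = "allometric")
  rp <- compute_resistive_powers(kin, area, athlete, atm, wvec, params)
  pw <- propulsive_power(kin, rp$P_drag, rp$P_roll, tuck,
                         smooth_window_s = smooth_window_s)
  structure(list(kinematics = kin, posture = post1, power = pw,
                 summary = summarize_race(pw), area = area,
                 athlete = athlete, env = env, params = params,
                 atm = atm, wind_vec = wvec),
            class = "race_analysis")
}

#' @export
print.race_analysis <- function(x, ...) {
  cat(sprintf("<race_analysis> %d s", nrow(x$power)))
  cat(sprintf(", %d lap(s)\n", max(x$power$lap)))
  print(x$summary)
  invisible(x)
}
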