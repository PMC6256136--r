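# IMU processing: axis alignment from a static pose, zero-phase moving
# averages, pitch-angle extraction, and tuck detection from gyroscope energy.

#' IMU stream container
#'
#' Wraps a torso- or thigh-mounted IMU recording. Axis convention: x =
#' mediolateral right, y = anterior, z completes the right-handed triad
#' (aligned with gravity when standing, after [align_axes()]). Units are
#' standardized internally to g for the accelerometer and deg/s for the
#' gyroscope, because the tuck threshold is defined in degree units.
#'
#' @param time seconds, strictly increasing (nominal 100 Hz).
#' @param accel n x 3 specific force.
#' @param gyro n x 3 angular rate.
#' @param location `"torso"` or `"thigh"`.
#' @param accel_units `"g"` or `"ms2"`.
#' @param gyro_units `"dps"` (deg/s) or `"rps"` (rad/s).
#' @return a list of class `imu_stream`.
#' @export
imu_stream <- function(time, accel, gyro, location = c("torso", "thigh"),
                       accel_units = c("g", "ms2"), gyro_units = c("dps", "rps")) {
  location <- match.arg(location)
  accel_units <- match.arg(accel_units)
  gyro_units <- match.arg(gyro_units)
  accel <- as_matrix3(accel); gyro <- as_matrix3(gyro)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  stopifnot(nrow(accel) == length(time), nrow(gyro) == length(time))
  if (accel_units == "ms2") accel <- accel / G_ACCEL
  if (gyro_units == "rps") gyro <- gyro * 180 / pi
  structure(list(time = time, accel = accel, gyro = gyro, location = location,
                 fs = 1 / stats::median(diff(time))),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %s, %d samples at %.0f Hz\n",
              x$location, length(x$time), x$fs))
  invisible(x)
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))

#' Align IMU axes using a static standing pose
#'
#' Estimates the sensor-to-segment rotation from the mean specific force in
#' a still window: a first rotation about the anterior (y) axis cancels
#' lateral tilt, a second about the mediolateral (x) axis cancels forward
#' tilt, leaving the mean specific force at (0, 0, +1 g). The rotation is
#' applied to both the accelerometer and the gyroscope. Idempotent: on an
#' already-aligned stream the recovered rotation is the identity.
#'
#' @param stream an [imu_stream()].
#' @param static_window `c(t0, t1)` seconds delimiting the still pose
#'   (>= 1 s; mean gyro magnitude must stay below `still_gyro_max`).
#' @param still_gyro_max stillness gate on the gyro magnitude (deg/s).
#' @return the aligned [imu_stream()] with the rotation in attribute
#'   `rotation`.
#' @export
align_axes <- function(stream, static_window, still_gyro_max = 10) {
  idx <- which(stream$time >= static_window[1] & stream$time <= static_window[2])
  if (length(idx) < 2 || diff(range(stream$time[idx])) < 1 - 1e-9) {
    stop("static window must span at least 1 s of samples")
  }
  gmag <- row_norm(stream$gyro[idx, , drop = FALSE])
  if (mean(gmag) >= still_gyro_max) {
    cand <- find_still_windows(stream, still_gyro_max)
    stop(sprintf(
      "window not still (mean |gyro| %.1f deg/s >= %g); candidate still windows: %s",
      mean(gmag), still_gyro_max,
      if (nrow(cand) == 0) "none found" else
        paste(sprintf("[%.1f, %.1f]", cand$t0, cand$t1), collapse = ", ")))
  }
  g_mean <- colMeans(stream$accel[idx, , drop = FALSE])
  # cancel lateral tilt (about y), then forward tilt (about x)
  phi <- atan2(g_mean[1], g_mean[3])
  g1 <- rot_y(-phi) %*% g_mean
  theta <- atan2(g1[2], g1[3])
  R <- rot_x(theta) %*% rot_y(-phi)
  out <- stream
  out$accel <- stream$accel %*% t(R)
  out$gyro <- stream$gyro %*% t(R)
  attr(out, "rotation") <- R
  out
}

# scan for >= 1 s windows whose mean gyro magnitude is below the gate
find_still_windows <- function(stream, still_gyro_max = 10) {
  gmag <- row_norm(stream$gyro)
  n1 <- max(3L, round(stream$fs))
  sm <- moving_average_pass(gmag, 2 * floor(n1 / 2) + 1)
  ok <- sm < still_gyro_max
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= n1
  data.frame(t0 = stream$time[starts[keep]], t1 = stream$time[ends[keep]])
}

#' Zero-phase moving average for IMU channels
#'
#' Thin wrapper over [smooth_ma()] using the stream's sampling rate; the
#' default 2 s window matches the smoothing applied to both the
#' accelerometer (before pitch angles) and the squared gyro magnitude
#' (before tuck detection).
#'
#' @param x numeric vector sampled at `fs` Hz.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @return smoothed vector.
#' @export
smooth_imu <- function(x, fs, window_s = 2.0) {
  smooth_ma(x, window_s = window_s, fs = fs)
}

#' Pitch angles from smoothed accelerometer output
#'
#' theta = atan2(a_y, a_z) on the smoothed, axis-aligned accelerometer:
#' 0 when upright, pi/2 when the segment is horizontal. atan2 (rather than
#' atan of the ratio) keeps the sign well defined when a_z <= 0; the result
#' is clamped to [-pi/2, pi/2] for the frontal-area model, whose cosine
#' needs a well-defined sign. Samples whose smoothed specific-force
#' magnitude falls below `min_accel_g` are flagged unreliable.
#'
#' @param stream an aligned [imu_stream()].
#' @param window_s smoothing window (s) applied to the accelerometer.
#' @param min_accel_g reliability gate on |a| (g).
#' @return numeric vector of pitch angles (rad) with attribute `unreliable`.
#' @export
pitch_angles <- function(stream, window_s = 2.0, min_accel_g = 0.2) {
  ay <- smooth_imu(stream$accel[, 2], stream$fs, window_s)
  az <- smooth_imu(stream$accel[, 3], stream$fs, window_s)
  amag <- sqrt(smooth_imu(stream$accel[, 1], stream$fs, window_s)^2 + ay^2 + az^2)
  theta <- atan2(ay, az)
  theta <- pmin(pmax(theta, -pi / 2), pi / 2)
  attr(theta, "unreliable") <- which(amag < min_accel_g)
  theta
}

#' Smoothed squared gyroscope magnitude
#'
#' smooth(|omega|^2) in deg^2/s^2: the squared magnitude is formed first,
#' then smoothed with the 2 s zero-phase moving average (the alternative
#' |smooth(omega)|^2 would cancel oscillatory rotation and is available via
#' `order = "smooth_first"`).
#'
#' @param stream an [imu_stream()].
#' @param window_s smoothing window (s).
#' @param order `"square_first"` (default) or `"smooth_first"`.
#' @return numeric vector (deg^2 s^-2).
#' @export
gyro_energy <- function(stream, window_s = 2.0,
                        order = c("square_first", "smooth_first")) {
  order <- match.arg(order)
  if (order == "square_first") {
    smooth_imu(rowSums(stream$gyro^2), stream$fs, window_s)
  } else {
    gs <- apply(stream$gyro, 2, smooth_imu, fs = stream$fs, window_s = window_s)
    rowSums(gs^2)
  }
}

#' Tuck detection from torso and thigh gyroscope energy
#'
#' The athlete is in the tuck position when the smoothed squared gyro
#' magnitudes of BOTH devices are strictly below the threshold
#' (default 5,000 deg^2 s^-2): every propulsive technique rotates the
#' thorax and thigh substantially, while the tuck keeps both still.
#'
#' @param gyro_sq_torso,gyro_sq_thigh smoothed squared gyro magnitudes
#'   (deg^2 s^-2) on a common timebase.
#' @param threshold tuck threshold (deg^2 s^-2).
#' @return logical vector.
#' @export
detect_tuck <- function(gyro_sq_torso, gyro_sq_thigh, threshold = 5000) {
  stopifnot(length(gyro_sq_torso) == length(gyro_sq_thigh))
  gyro_sq_torso < threshold & gyro_sq_thigh < threshold
}

#' Build a posture series from torso and thigh IMU streams
#'
#' Runs smoothing, pitch extraction and gyro-energy computation on both
#' streams over their common time range and combines them into one series
#' with a tuck flag.
#'
#' @param torso,thigh aligned [imu_stream()] objects.
#' @param window_s smoothing window (s).
#' @param threshold tuck threshold (deg^2 s^-2).
#' @return data frame of class `posture_series`: `time`, `theta_torso`,
#'   `theta_thigh`, `gyro_sq_torso`, `gyro_sq_thigh`, `tuck`.
#' @export
posture_series <- function(torso, thigh, window_s = 2.0, threshold = 5000) {
  t0 <- max(torso$time[1], thigh$time[1])
  t1 <- min(torso$time[length(torso$time)], thigh$time[length(thigh$time)])
  if (t1 <= t0) stop("torso and thigh streams have non-overlapping time ranges")
  th_to <- pitch_angles(torso, window_s)
  th_th <- pitch_angles(thigh, window_s)
  gq_to <- gyro_energy(torso, window_s)
  gq_th <- gyro_energy(thigh, window_s)
  keep_to <- torso$time >= t0 & torso$time <= t1
  tt <- torso$time[keep_to]
  # thigh channels interpolated onto the torso timebase (devices free-run)
  interp <- function(v, tm) stats::approx(tm, v, xout = tt, rule = 2)$y
  out <- data.frame(
    time = tt,
    theta_torso = th_to[keep_to],
    theta_thigh = interp(th_th, thigh$time),
    gyro_sq_torso = gq_to[keep_to],
    gyro_sq_thigh = interp(gq_th, thigh$time))
  out$tuck <- detect_tuck(out$gyro_sq_torso, out$gyro_sq_thigh, threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("posture_series", "data.frame")
  out
}

#' Aggregate a posture series onto a 1 Hz kinematic timebase
#'
#' Power is computed at 1 Hz while posture is sampled at ~100 Hz; each
#' kinematic time stamp receives the mean of the posture channels over the
#' surrounding 1 s interval, and the tuck flag is re-derived by applying
#' the threshold to the bin-averaged gyro energies.
#'
#' @param posture a [posture_series()].
#' @param times 1 Hz time stamps (s).
#' @param threshold tuck threshold (deg^2 s^-2).
#' @return data frame with one row per entry of `times`.
#' @export
aggregate_posture <- function(posture, times,
                              threshold = attr(posture, "threshold") %||% 5000) {
  bin <- findInterval(posture$time, c(times - 0.5, Inf))
  ok <- bin >= 1 & bin <= length(times)
  agg <- function(v) {
    m <- tapply(v[ok], bin[ok], mean)
    out <- rep(NA_real_, length(times))
    out[as.integer(names(m))] <- m
    # extend edge values where the IMU does not cover the bin
    if (anyNA(out)) out <- stats::approx(which(!is.na(out)), out[!is.na(out)],
                                         xout = seq_along(out), rule = 2)$y
    out
  }
  out <- data.frame(
    time = times,
    theta_torso = agg(posture$theta_torso),
    theta_thigh = agg(posture$theta_thigh),
    gyro_sq_torso = agg(posture$gyro_sq_torso),
    gyro_sq_thigh = agg(posture$gyro_sq_thigh))
  out$tuck <- detect_tuck(out$gyro_sq_torso, out$gyro_sq_thigh, threshold)
  out
}
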