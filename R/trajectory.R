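# Trajectory processing: geodetic conversion, reference-track resampling and
# smoothing, zero-phase low-pass filtering, arc-length map matching, finite
# differences, curvature, and assembly of 1 Hz center-of-mass kinematics.

# WGS84 ellipsoid
WGS84_A <- 6378137.0
WGS84_F <- 1 / 298.257223563
WGS84_E2 <- WGS84_F * (2 - WGS84_F)

geodetic_to_ecef <- function(lat_deg, lon_deg, h) {
  lat <- lat_deg * pi / 180
  lon <- lon_deg * pi / 180
  N <- WGS84_A / sqrt(1 - WGS84_E2 * sin(lat)^2)
  cbind((N + h) * cos(lat) * cos(lon),
        (N + h) * cos(lat) * sin(lon),
        (N * (1 - WGS84_E2) + h) * sin(lat))
}

enu_rotation <- function(lat_deg, lon_deg) {
  lat <- lat_deg * pi / 180
  lon <- lon_deg * pi / 180
  rbind(c(-sin(lon), cos(lon), 0),
        c(-sin(lat) * cos(lon), -sin(lat) * sin(lon), cos(lat)),
        c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat)))
}

#' Convert geodetic coordinates to a local east-north-up frame
#'
#' Positions are converted to WGS84 earth-centered earth-fixed coordinates
#' and rotated into the tangent plane anchored at `origin`, which maps to
#' (0, 0, 0). The transform is exact and invertible (see
#' [from_local_frame()]); over a ~10 km course extent chord distances match
#' geodesic distances to well below 0.01 %.
#'
#' @param lat_deg,lon_deg,ele_m geodetic latitude (deg), longitude (deg) and
#'   ellipsoidal height (m) of the points to convert.
#' @param origin numeric length-3 vector `c(lat_deg, lon_deg, ele_m)` of the
#'   frame anchor (defaults to the first point).
#' @return an n x 3 matrix of ENU coordinates (m) with the origin stored in
#'   the `origin` attribute.
#' @export
to_local_frame <- function(lat_deg, lon_deg, ele_m, origin = NULL) {
  bad <- which(lat_deg < -90 | lat_deg > 90 | lon_deg < -180 | lon_deg > 180)
  if (length(bad) > 0) {
    stop(sprintf("out-of-range geodetic coordinates at sample(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (is.null(origin)) origin <- c(lat_deg[1], lon_deg[1], ele_m[1])
  ecef <- geodetic_to_ecef(lat_deg, lon_deg, ele_m)
  ecef0 <- geodetic_to_ecef(origin[1], origin[2], origin[3])
  R <- enu_rotation(origin[1], origin[2])
  enu <- sweep(ecef, 2, as.numeric(ecef0)) %*% t(R)
  colnames(enu) <- c("x", "y", "z")
  attr(enu, "origin") <- origin
  enu
}

#' Convert local ENU coordinates back to geodetic
#'
#' Exact inverse of [to_local_frame()] (iterative geodetic latitude
#' recovery, converged to < 1e-9 m).
#'
#' @param enu n x 3 ENU matrix (m).
#' @param origin length-3 `c(lat_deg, lon_deg, ele_m)` anchor.
#' @return data frame with `lat_deg`, `lon_deg`, `ele_m`.
#' @export
from_local_frame <- function(enu, origin = attr(enu, "origin")) {
  if (is.null(origin)) stop("origin required")
  enu <- as_matrix3(enu)
  R <- enu_rotation(origin[1], origin[2])
  ecef0 <- geodetic_to_ecef(origin[1], origin[2], origin[3])
  ecef <- enu %*% R + matrix(as.numeric(ecef0), nrow(enu), 3, byrow = TRUE)
  X <- ecef[, 1]; Y <- ecef[, 2]; Z <- ecef[, 3]
  lon <- atan2(Y, X)
  p <- sqrt(X^2 + Y^2)
  lat <- atan2(Z, p * (1 - WGS84_E2))
  for (i in 1:8) {
    N <- WGS84_A / sqrt(1 - WGS84_E2 * sin(lat)^2)
    h <- p / cos(lat) - N
    lat <- atan2(Z, p * (1 - WGS84_E2 * N / (N + h)))
  }
  N <- WGS84_A / sqrt(1 - WGS84_E2 * sin(lat)^2)
  h <- p / cos(lat) - N
  data.frame(lat_deg = lat * 180 / pi, lon_deg = lon * 180 / pi, ele_m = h)
}

#' Resample a track to equidistant arc-length spacing
#'
#' The input polyline is re-parameterized by cumulative chord length and
#' linearly interpolated at multiples of `spacing` (nominally 1 m), so that
#' every output point lies on the piecewise-linear input curve.
#' `fix_quality` is inherited from the nearest source point.
#'
#' @param track a `geo_trajectory` or any data frame with `x`, `y`, `z`
#'   (and optionally `fix_quality`).
#' @param spacing target arc-length spacing (m).
#' @param closed mark the output as a closed loop.
#' @return a [reference_track()].
#' @export
resample_reference <- function(track, spacing = 1.0, closed = FALSE) {
  xyz <- as.matrix(track[, c("x", "y", "z")])
  if (nrow(xyz) < 3) stop("need at least 3 points to resample")
  seg <- sqrt(rowSums(diff(xyz)^2))
  if (all(seg < 1e-12)) stop("degenerate track: all points coincident")
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < 2 * spacing) stop("cumulative chord length shorter than 2 * spacing")
  s_out <- seq(0, total, by = spacing)
  out <- vapply(1:3, function(k) stats::approx(cum, xyz[, k], xout = s_out)$y,
                numeric(length(s_out)))
  fq <- if ("fix_quality" %in% names(track)) {
    idx <- vapply(s_out, function(s) which.min(abs(cum - s)), integer(1))
    track$fix_quality[idx]
  } else rep("fixed", length(s_out))
  reference_track(s_out, out[, 1], out[, 2], out[, 3], fq, closed = closed)
}

#' Cubic smoothing spline with the penalized-residual convention
#'
#' Minimizes `p * sum(w_i (y_i - f(x_i))^2) + (1 - p) * integral(f'')^2`
#' over natural cubic splines with knots at the data sites (Reinsch
#' algorithm, sparse banded solve). `p = 1` interpolates; `p -> 0`
#' approaches the weighted least-squares straight line. `x` is used in its
#' original units, so `p` is directly comparable across tracks.
#'
#' @param x strictly increasing abscissae.
#' @param y observations.
#' @param w positive weights.
#' @param p smoothing parameter in (0, 1].
#' @return fitted values at `x`.
#' @export
penalized_spline <- function(x, y, w = rep(1, length(x)), p = 0.02) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n, n >= 3, p > 0, p <= 1)
  if (any(w <= 0)) stop("weights must be positive")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (p == 1) return(y)
  lambda <- (1 - p) / p
  h <- diff(x)
  i <- seq_len(n - 2)
  # Q: n x (n-2) second-difference matrix; R: (n-2) x (n-2) tridiagonal
  Q <- Matrix::sparseMatrix(
    i = c(i, i + 1, i + 2), j = rep(i, 3),
    x = c(1 / h[i], -(1 / h[i] + 1 / h[i + 1]), 1 / h[i + 1]),
    dims = c(n, n - 2))
  Rm <- Matrix::bandSparse(
    n - 2, n - 2, k = c(-1, 0, 1),
    diagonals = list(h[i + 1][-(n - 2)] / 6,
                     (h[i] + h[i + 1]) / 3,
                     h[i + 1][-(n - 2)] / 6),
    symmetric = FALSE)
  Winv <- Matrix::Diagonal(n, 1 / w)
  A <- Rm + lambda * Matrix::crossprod(Q, Winv %*% Q)
  cc <- Matrix::solve(A, Matrix::crossprod(Q, y))
  as.numeric(y - lambda * (Winv %*% (Q %*% cc)))
}

#' Smooth a reference track with fix-quality-weighted splines
#'
#' Each ENU coordinate is smoothed against arc length with
#' [penalized_spline()]; survey points with float carrier-phase ambiguities
#' receive a much smaller weight than fixed points so the smoothed curve
#' stays close to the reliable geometry. The result is re-resampled to the
#' original spacing so the arc-length parameterization stays consistent.
#'
#' @param track a [reference_track()].
#' @param p smoothing parameter (see [penalized_spline()]).
#' @param weight_fixed,weight_float weights assigned to fixed/float points.
#' @param weights optional explicit per-point weights (overrides the flags).
#' @return a smoothed [reference_track()].
#' @export
smooth_reference <- function(track, p = 0.02, weight_fixed = 1.0,
                             weight_float = 0.01, weights = NULL) {
  if (is.null(weights)) {
    weights <- ifelse(track$fix_quality == "float", weight_float, weight_fixed)
  }
  if (any(weights <= 0)) stop("weights must be positive")
  sm <- track
  for (k in c("x", "y", "z")) {
    sm[[k]] <- penalized_spline(track$s, track[[k]], weights, p)
  }
  spacing <- stats::median(diff(track$s))
  out <- resample_reference(sm, spacing = spacing,
                            closed = isTRUE(attr(track, "closed")))
  out
}

#' Zero-phase Butterworth low-pass filter for position streams
#'
#' Second-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and the squared magnitude
#' response of the one-pass filter. The series is mirror-padded before
#' filtering to suppress edge transients.
#'
#' @param traj a [geo_trajectory()] with uniform sampling.
#' @param cutoff_hz cutoff frequency (Hz); must be below Nyquist.
#' @param order filter order of each pass.
#' @return a filtered [geo_trajectory()].
#' @export
lowpass_positions <- function(traj, cutoff_hz = 0.3, order = 2) {
  dt <- diff(traj$time)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 0.25 * dt0)) {
    stop("non-uniform sampling: split the trajectory at gaps before filtering")
  }
  fs <- 1 / dt0
  if (cutoff_hz >= fs / 2) stop("cutoff frequency must be below Nyquist")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # renormalize so the DC gain is exactly 1
  bf$b <- bf$b * sum(bf$a) / sum(bf$b)
  out <- traj
  # generous pad: the filter starts from rest, so its internal transient
  # must decay fully inside the padded region
  npad <- min(nrow(traj) - 1, ceiling(10 * fs / cutoff_hz))
  for (k in c("x", "y", "z")) {
    v <- traj[[k]]
    # odd (point-reflected) padding as used by standard filtfilt implementations
    pre <- 2 * v[1] - v[(npad + 1):2]
    post <- 2 * v[length(v)] - v[(length(v) - 1):(length(v) - npad)]
    f <- signal::filtfilt(bf, c(pre, v, post))
    out[[k]] <- f[(npad + 1):(npad + length(v))]
  }
  out
}

# Project a single horizontal query point onto the reference polyline.
# cand: candidate vertex indices to consider. Returns list(s, z, dist).
project_point <- function(qx, qy, ref, cand, closed = FALSE, lap_length = NA) {
  n <- nrow(ref)
  d2 <- (ref$x[cand] - qx)^2 + (ref$y[cand] - qy)^2
  # nearest vertex, smallest arc length on ties
  best <- cand[order(d2, ref$s[cand])[1]]
  # refine on the two segments adjacent to the nearest vertex
  segs <- list()
  add_seg <- function(i, j, wrap) segs[[length(segs) + 1]] <<- c(i, j, wrap)
  if (best > 1) add_seg(best - 1, best, 0)
  if (best < n) add_seg(best, best + 1, 0)
  if (closed) {
    if (best == 1) add_seg(n, 1, 1)
    if (best == n) add_seg(n, 1, 1)
  }
  out <- c(s = ref$s[best], z = ref$z[best],
           dist = sqrt((ref$x[best] - qx)^2 + (ref$y[best] - qy)^2))
  for (sg in segs) {
    i <- sg[1]; j <- sg[2]
    ex <- ref$x[j] - ref$x[i]; ey <- ref$y[j] - ref$y[i]
    L2 <- ex^2 + ey^2
    if (L2 < 1e-12) next
    t <- ((qx - ref$x[i]) * ex + (qy - ref$y[i]) * ey) / L2
    t <- min(max(t, 0), 1)
    px <- ref$x[i] + t * ex; py <- ref$y[i] + t * ey
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    seg_len <- if (sg[3] == 1) {
      sqrt(ex^2 + ey^2 + (ref$z[j] - ref$z[i])^2)
    } else ref$s[j] - ref$s[i]
    s_here <- ref$s[i] + t * seg_len
    if (sg[3] == 1 && !is.na(lap_length)) s_here <- s_here %% lap_length
    if (d < out["dist"] - 1e-12 ||
        (abs(d - out["dist"]) <= 1e-12 && s_here < out["s"])) {
      out <- c(s = s_here, z = ref$z[i] + t * (ref$z[j] - ref$z[i]), dist = d)
    }
  }
  out
}

#' Map a horizontal position onto the reference trajectory
#'
#' Finds the point on the reference centerline minimizing horizontal-plane
#' Euclidean distance to the query (nearest vertex, refined by linear
#' interpolation on the adjacent segments) and returns the reference height
#' there. Ties are broken toward the smaller arc length. The search may be
#' restricted to an arc-length window, which is how lapped, self-crossing
#' courses are disambiguated (see [project_trajectory()]).
#'
#' @param xy length-2 numeric `c(x, y)` query (m).
#' @param ref a [reference_track()].
#' @param window optional `c(s_min, s_max)` arc-length search window (m);
#'   on closed tracks it may wrap past the lap end.
#' @param gate maximum accepted horizontal distance (m); beyond it the
#'   sample is flagged unmapped (`mapped = FALSE`).
#' @return list with `s` (m), `z` (m), `dist` (m), `mapped` (logical).
#' @export
map_to_reference <- function(xy, ref, window = NULL, gate = 20) {
  n <- nrow(ref)
  closed <- isTRUE(attr(ref, "closed"))
  lap_length <- attr(ref, "lap_length") %||% NA
  cand <- seq_len(n)
  if (!is.null(window)) {
    if (closed) {
      w0 <- window[1] %% lap_length; w1 <- window[2] %% lap_length
      cand <- if (window[2] - window[1] >= lap_length) seq_len(n)
              else if (w0 <= w1) which(ref$s >= w0 & ref$s <= w1)
              else which(ref$s >= w0 | ref$s <= w1)
    } else {
      cand <- which(ref$s >= window[1] & ref$s <= window[2])
    }
    if (length(cand) == 0) stop("empty search window")
  }
  pr <- project_point(xy[1], xy[2], ref, cand, closed, lap_length)
  list(s = unname(pr["s"]), z = unname(pr["z"]), dist = unname(pr["dist"]),
       mapped = unname(pr["dist"]) <= gate)
}

#' Project a whole trajectory onto the reference with monotone windowing
#'
#' Because the course is lapped and self-crossing, each sample after the
#' first is matched inside a sliding arc-length window centered on the
#' previous match and advanced monotonically; the first sample searches
#' globally. On closed tracks the arc position is unwrapped across laps, so
#' the returned `s_total` is monotone over the whole recording.
#'
#' @param traj a [geo_trajectory()].
#' @param ref a [reference_track()].
#' @param window half-width of the sliding arc-length window (m).
#' @param gate unmapped-distance gate (m), see [map_to_reference()].
#' @return data frame `s` (within-lap, m), `s_total` (unwrapped, m),
#'   `z` (m), `dist` (m), `mapped`, `lap` (1-based).
#' @export
project_trajectory <- function(traj, ref, window = 200, gate = 20) {
  n <- nrow(traj)
  closed <- isTRUE(attr(ref, "closed"))
  lap_length <- attr(ref, "lap_length") %||% (max(ref$s) + stats::median(diff(ref$s)))
  s <- z <- dist <- numeric(n)
  mapped <- logical(n)
  s_total <- numeric(n)
  prev_total <- NA
  for (i in seq_len(n)) {
    win <- if (is.na(prev_total)) NULL else {
      center <- prev_total %% lap_length
      c(center - window, center + window)
    }
    m <- map_to_reference(c(traj$x[i], traj$y[i]), ref, window = win, gate = gate)
    s[i] <- m$s; z[i] <- m$z; dist[i] <- m$dist; mapped[i] <- m$mapped
    if (is.na(prev_total)) {
      s_total[i] <- m$s
    } else {
      # smallest unwrapped move consistent with the within-lap position
      base <- floor(prev_total / lap_length) * lap_length
      cands <- base + m$s + c(-lap_length, 0, lap_length)
      # forbid going backwards by more than the window
      cands <- cands[cands >= prev_total - window]
      s_total[i] <- cands[which.min(abs(cands - prev_total))]
    }
    if (mapped[i]) prev_total <- s_total[i]
  }
  data.frame(s = s, s_total = s_total, z = z, dist = dist, mapped = mapped,
             lap = pmin(floor(s_total / lap_length) + 1L,
                        .Machine$integer.max))
}

# five-point stencils: interior central + one-sided at the edges
FD5_EDGE <- rbind(c(-25, 48, -36, 16, -3),
                  c(-3, -10, 18, -6, 1)) / 12

#' Five-point finite-difference derivative
#'
#' Interior points use the central five-point stencil
#' `(f[i-2] - 8 f[i-1] + 8 f[i+1] - f[i+2]) / (12 dt)`; the first and last
#' two points use one-sided five-point stencils. Exact for polynomials of
#' degree <= 4.
#'
#' @param x uniformly sampled values (vector or matrix; columns
#'   differentiated independently).
#' @param dt sampling interval (s).
#' @return derivative, same shape as `x`.
#' @export
finite_difference <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2, finite_difference, dt = dt))
  n <- length(x)
  if (n < 5) stop("need at least 5 samples for the five-point stencil")
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (x[i - 2] - 8 * x[i - 1] + 8 * x[i + 1] - x[i + 2]) / (12 * dt)
  d[1] <- sum(FD5_EDGE[1, ] * x[1:5]) / dt
  d[2] <- sum(FD5_EDGE[2, ] * x[1:5]) / dt
  d[n] <- -sum(FD5_EDGE[1, ] * x[n:(n - 4)]) / dt
  d[n - 1] <- -sum(FD5_EDGE[2, ] * x[n:(n - 4)]) / dt
  d
}

#' Track curvature vector from velocity and acceleration
#'
#' `K = -v x (v x a) / |v|^4`. For circular motion `|K| = 1/r` and `K`
#' points toward the center; for rectilinear motion `K = 0`. Below the
#' speed floor the curvature is set to zero and the sample flagged, since
#' the formula blows up at standstill.
#'
#' @param v n x 3 velocity (m/s).
#' @param a n x 3 acceleration (m/s^2).
#' @param speed_floor minimum speed (m/s) for a valid curvature.
#' @return n x 3 curvature matrix (1/m) with attribute `flagged` marking
#'   below-floor samples.
#' @export
curvature <- function(v, a, speed_floor = 0.5) {
  v <- as_matrix3(v); a <- as_matrix3(a)
  sp <- row_norm(v)
  K <- -row_cross(v, row_cross(v, a)) / pmax(sp, 1e-12)^4
  low <- sp < speed_floor
  K[low, ] <- 0
  attr(K, "flagged") <- which(low)
  K
}

#' Assemble 1 Hz center-of-mass kinematics
#'
#' The filtered athlete stream supplies horizontal position and velocity;
#' vertical position (and hence vertical velocity and inclination) comes
#' from the reference trajectory through map matching, which is far more
#' accurate than standalone GNSS height. The mapped series is down-sampled
#' to 1 Hz by decimation (the 0.3 Hz low-pass already bounds the
#' bandwidth), then differentiated with five-point stencils.
#'
#' @param traj a low-pass-filtered [geo_trajectory()].
#' @param ref a [reference_track()]; `NULL` uses the standalone GNSS height
#'   directly (the degraded pathway, for comparison studies).
#' @param fs_out output rate (Hz), default 1.
#' @param window,gate map-matching parameters, see [project_trajectory()].
#' @param speed_floor floor (m/s) for curvature and downstream divisions.
#' @param max_unmapped_frac error threshold on the unmapped-sample fraction.
#' @return a data frame of class `kinematic_series`: `time`, `x`, `y`, `z`,
#'   `vx`, `vy`, `vz`, `speed`, `accel_along`, `incline`, `curv_x`,
#'   `curv_y`, `curv_z`, `s`, `s_total`, `lap`, `mapped`.
#' @export
build_kinematics <- function(traj, ref, fs_out = 1, window = 200, gate = 20,
                             speed_floor = 0.5, max_unmapped_frac = 0.1) {
  if (!is.null(ref)) {
    prj <- project_trajectory(traj, ref, window = window, gate = gate)
    if (mean(!prj$mapped) > max_unmapped_frac) {
      stop(sprintf("%.1f%% of samples farther than the %g m gate from the reference",
                   100 * mean(!prj$mapped), gate))
    }
    z_use <- prj$z
  } else {
    prj <- NULL
    z_use <- traj$z
  }
  # decimate to fs_out
  dt_in <- stats::median(diff(traj$time))
  step <- max(1L, round(1 / (fs_out * dt_in)))
  idx <- seq(1L, nrow(traj), by = step)
  t1 <- traj$time[idx]
  dt <- stats::median(diff(t1))
  pos <- cbind(traj$x[idx], traj$y[idx], z_use[idx])
  vel <- finite_difference(pos, dt)
  acc <- finite_difference(vel, dt)
  speed <- row_norm(vel)
  vhat <- vel / pmax(speed, 1e-12)
  accel_along <- rowSums(acc * vhat)
  vh <- sqrt(vel[, 1]^2 + vel[, 2]^2)
  incline <- atan2(vel[, 3], pmax(vh, 1e-12))
  K <- curvature(vel, acc, speed_floor = speed_floor)
  out <- data.frame(time = t1, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
                    speed = speed, accel_along = accel_along,
                    incline = incline,
                    curv_x = K[, 1], curv_y = K[, 2], curv_z = K[, 3])
  if (!is.null(prj)) {
    out$s <- prj$s[idx]; out$s_total <- prj$s_total[idx]
    out$lap <- prj$lap[idx]; out$mapped <- prj$mapped[idx]
  } else {
    horiz <- c(0, cumsum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)))
    out$s <- horiz[idx]; out$s_total <- horiz[idx]
    out$lap <- 1L; out$mapped <- TRUE
  }
  attr(out, "speed_floor") <- speed_floor
  class(out) <- c("kinematic_series", "data.frame")
  out
}
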