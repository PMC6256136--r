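#' GNSS trajectory container
#'
#' A `geo_trajectory` is a data frame with columns `time` (s, strictly
#' increasing), `x`, `y`, `z` (local east-north-up metric coordinates, m)
#' and optionally `fix_quality` (`"fixed"` or `"float"`, reference
#' trajectories only). Sampling gaps are detected against the nominal rate
#' and flagged in the `gap_after` attribute; they are never interpolated.
#'
#' @param time numeric vector of seconds, strictly increasing.
#' @param x,y,z east, north, up coordinates in meters.
#' @param fix_quality optional character vector, `"fixed"` or `"float"`.
#' @param nominal_hz nominal sampling rate used for gap detection.
#' @return a data frame of class `geo_trajectory`.
#' @export
geo_trajectory <- function(time, x, y, z, fix_quality = NULL, nominal_hz = 10) {
  stopifnot(length(time) == length(x), length(x) == length(y), length(y) == length(z))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!all(is.finite(c(x, y, z)))) stop("all coordinates must be finite")
  df <- data.frame(time = time, x = x, y = y, z = z)
  if (!is.null(fix_quality)) {
    fix_quality <- match.arg(fix_quality, c("fixed", "float"), several.ok = TRUE)
    df$fix_quality <- fix_quality
  }
  dt_nom <- 1 / nominal_hz
  attr(df, "nominal_hz") <- nominal_hz
  attr(df, "gap_after") <- which(diff(time) > 3 * dt_nom)
  class(df) <- c("geo_trajectory", "data.frame")
  df
}

#' Reference track container
#'
#' An arc-length-parameterized course centerline: columns `s` (m, monotone,
#' nominal 1 m spacing), `x`, `y`, `z` (ENU m) and `fix_quality` inherited
#' from the source survey points. A closed (lapped) course is marked with
#' the `closed` attribute; its `lap_length` is the total perimeter.
#'
#' @param s arc length in meters, strictly increasing from 0.
#' @param x,y,z ENU coordinates (m).
#' @param fix_quality character vector (`"fixed"`/`"float"`).
#' @param closed logical; TRUE when the track is a closed loop.
#' @return a data frame of class `reference_track`.
#' @export
reference_track <- function(s, x, y, z, fix_quality = rep("fixed", length(s)),
                            closed = FALSE) {
  stopifnot(length(s) == length(x))
  if (any(diff(s) <= 0)) stop("arc length must be strictly increasing")
  df <- data.frame(s = s, x = x, y = y, z = z, fix_quality = fix_quality)
  class(df) <- c("reference_track", "data.frame")
  attr(df, "closed") <- closed
  if (closed) {
    # perimeter includes the closing segment from the last point back to the first
    last_seg <- sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2 +
                       (z[1] - z[length(z)])^2)
    attr(df, "lap_length") <- s[length(s)] + last_seg
  }
  df
}

#' Athlete model parameters
#'
#' Bundles the per-athlete physical parameters used by the force models:
#' total mass (athlete + equipment), rolling-resistance coefficient and its
#' uncertainty, standing frontal area, and characteristic width for the
#' Reynolds number.
#'
#' @param mass_kg total mass of athlete plus equipment (kg).
#' @param crr coefficient of rolling resistance (dimensionless).
#' @param crr_sd standard deviation of `crr` for uncertainty propagation.
#' @param A0_m2 standing frontal area (m^2).
#' @param L_m characteristic width in the pelvis/abdomen region (m).
#' @return a list of class `athlete_model`.
#' @export
athlete_model <- function(mass_kg = 77.1, crr = 0.0225, crr_sd = 2.3e-3,
                          A0_m2 = 0.55, L_m = 0.30) {
  stopifnot(mass_kg > 0, crr > 0, crr_sd >= 0, A0_m2 > 0, L_m > 0)
  structure(list(mass_kg = mass_kg, crr = crr, crr_sd = crr_sd,
                 A0_m2 = A0_m2, L_m = L_m),
            class = "athlete_model")
}

#' Environment record
#'
#' Atmospheric state and hourly wind used by the drag model. Wind follows
#' the meteorological convention: `wind_dir_deg` is the direction the wind
#' comes FROM, clockwise from north.
#'
#' @param temp_C air temperature (deg C).
#' @param pressure_kPa air pressure (kPa).
#' @param wind10m_ms hourly mean wind speed at 10 m above ground (m/s).
#' @param wind_dir_deg meteorological wind direction (deg).
#' @param z0 roughness length for the log wind profile (m).
#' @param wind_height_m height above ground the athlete-level wind refers to (m).
#' @return a list of class `environment_record`.
#' @export
environment_record <- function(temp_C = 12.5, pressure_kPa = 96.6,
                               wind10m_ms = 0, wind_dir_deg = 0,
                               z0 = 0.1, wind_height_m = 1.0) {
  stopifnot(wind10m_ms >= 0, z0 > 0, wind_height_m > z0)
  structure(list(temp_C = temp_C, pressure_kPa = pressure_kPa,
                 wind10m_ms = wind10m_ms, wind_dir_deg = wind_dir_deg,
                 z0 = z0, wind_height_m = wind_height_m),
            class = "environment_record")
}

#' @export
print.athlete_model <- function(x, ...) {
  cat(sprintf("<athlete_model> mass %.1f kg, Crr %.4f (sd %.1e), A0 %.3f m^2, L %.2f m\n",
              x$mass_kg, x$crr, x$crr_sd, x$A0_m2, x$L_m))
  invisible(x)
}

#' @export
print.geo_trajectory <- function(x, ...) {
  cat(sprintf("<geo_trajectory> %d samples, %.1f s, %d gap(s)\n",
              nrow(x), diff(range(x$time)), length(attr(x, "gap_after"))))
  invisible(x)
}

#' @export
print.reference_track <- function(x, ...) {
  cat(sprintf("<reference_track> %d points, %.0f m%s, %d float point(s)\n",
              nrow(x), max(x$s),
              if (isTRUE(attr(x, "closed"))) sprintf(" (closed loop, lap %.0f m)", attr(x, "lap_length")) else "",
              sum(x$fix_quality == "float")))
  invisible(x)
}
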