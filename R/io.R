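# Readers and writers for the supported plain-text formats (CSV, GPX,
# YAML config, JSON summaries). Every writer's output is readable by its
# paired reader with lossless round-trip of the declared fields.

#' Read a GNSS stream from CSV
#'
#' Accepts either `time_s,lat_deg,lon_deg,ele_m` (geodetic; converted to a
#' local ENU frame anchored at `origin` or the first point) or
#' `time_s,x_m,y_m,z_m` (already metric). An optional `fix_quality` column
#' is carried through.
#'
#' @param path CSV file path.
#' @param origin optional `c(lat_deg, lon_deg, ele_m)` anchor for geodetic
#'   input.
#' @param nominal_hz nominal sampling rate for gap flagging.
#' @return a [geo_trajectory()].
#' @export
read_gnss_csv <- function(path, origin = NULL, nominal_hz = 10) {
  df <- utils::read.csv(path, comment.char = "#")
  fq <- df$fix_quality
  if (all(c("lat_deg", "lon_deg", "ele_m") %in% names(df))) {
    enu <- to_local_frame(df$lat_deg, df$lon_deg, df$ele_m, origin = origin)
    out <- geo_trajectory(df$time_s, enu[, 1], enu[, 2], enu[, 3],
                          fix_quality = fq, nominal_hz = nominal_hz)
    attr(out, "origin") <- attr(enu, "origin")
  } else if (all(c("x_m", "y_m", "z_m") %in% names(df))) {
    out <- geo_trajectory(df$time_s, df$x_m, df$y_m, df$z_m,
                          fix_quality = fq, nominal_hz = nominal_hz)
  } else {
    stop(sprintf("%s: expected columns time_s + (lat_deg,lon_deg,ele_m) or (x_m,y_m,z_m)",
                 path))
  }
  out
}

#' Write a GNSS stream (or any trajectory) to CSV
#'
#' @param traj a [geo_trajectory()].
#' @param path output path.
#' @export
write_gnss_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$time, x_m = traj$x, y_m = traj$y, z_m = traj$z)
  if (!is.null(traj$fix_quality)) df$fix_quality <- traj$fix_quality
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a reference track from CSV
#'
#' If the file carries an `s_m` column it is taken as an already
#' arc-length-parameterized track; otherwise the points are resampled to
#' `spacing`.
#'
#' @param path CSV with `x_m,y_m,z_m,fix_quality` (and optionally `s_m`).
#' @param spacing resampling spacing (m).
#' @param closed closed-loop flag.
#' @return a [reference_track()].
#' @export
read_reference_csv <- function(path, spacing = 1.0, closed = TRUE) {
  df <- utils::read.csv(path, comment.char = "#")
  fq <- df$fix_quality %||% rep("fixed", nrow(df))
  if ("s_m" %in% names(df)) {
    reference_track(df$s_m, df$x_m, df$y_m, df$z_m, fq, closed = closed)
  } else {
    resample_reference(data.frame(x = df$x_m, y = df$y_m, z = df$z_m,
                                  fix_quality = fq),
                       spacing = spacing, closed = closed)
  }
}

#' @rdname read_reference_csv
#' @param track a [reference_track()].
#' @export
write_reference_csv <- function(track, path) {
  utils::write.csv(data.frame(s_m = track$s, x_m = track$x, y_m = track$y,
                              z_m = track$z, fix_quality = track$fix_quality),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read an IMU stream from CSV
#'
#' Format: a comment line `# accel_units=<g|ms2> gyro_units=<dps|rps>`
#' followed by a CSV with columns `time_s,ax,ay,az,gx,gy,gz,location`.
#'
#' @param path CSV file path.
#' @return an [imu_stream()].
#' @export
read_imu_csv <- function(path) {
  first <- readLines(path, n = 1)
  accel_units <- "g"; gyro_units <- "dps"
  if (startsWith(first, "#")) {
    au <- regmatches(first, regexpr("accel_units=\\w+", first))
    gu <- regmatches(first, regexpr("gyro_units=\\w+", first))
    if (length(au)) accel_units <- sub("accel_units=", "", au)
    if (length(gu)) gyro_units <- sub("gyro_units=", "", gu)
  }
  df <- utils::read.csv(path, comment.char = "#")
  imu_stream(df$time_s, as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("gx", "gy", "gz")]),
             location = as.character(df$location[1]),
             accel_units = accel_units, gyro_units = gyro_units)
}

#' @rdname read_imu_csv
#' @param stream an [imu_stream()] (written in g and deg/s).
#' @export
write_imu_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# accel_units=g gyro_units=dps", con)
  utils::write.csv(data.frame(time_s = stream$time,
                              ax = stream$accel[, 1], ay = stream$accel[, 2],
                              az = stream$accel[, 3],
                              gx = stream$gyro[, 1], gy = stream$gyro[, 2],
                              gz = stream$gyro[, 3],
                              location = stream$location),
                   con, row.names = FALSE, quote = FALSE)
}

#' Read hourly environment records from CSV
#'
#' Columns: `time_iso,temp_C,pressure_kPa,wind10m_ms,wind_dir_deg`.
#' [env_at()] picks the nearest hourly row for a given time.
#'
#' @param path CSV file path.
#' @return data frame with a POSIXct `time` column.
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  tm <- as.POSIXct(df$time_iso, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(tm)) stop("unparseable or timezone-naive time_iso values")
  df$time <- tm
  df
}

#' Nearest-hour environment lookup
#'
#' @param env_table output of [read_env_csv()].
#' @param time a POSIXct time.
#' @return an [environment_record()].
#' @export
env_at <- function(env_table, time) {
  i <- which.min(abs(as.numeric(env_table$time) - as.numeric(time)))
  environment_record(temp_C = env_table$temp_C[i],
                     pressure_kPa = env_table$pressure_kPa[i],
                     wind10m_ms = env_table$wind10m_ms[i],
                     wind_dir_deg = env_table$wind_dir_deg[i])
}

#' Read a GPX 1.1 track
#'
#' Parses `trkpt` latitude/longitude/elevation/time and converts to a
#' local ENU frame. Point times are converted to elapsed seconds from the
#' first point.
#'
#' @param path GPX file.
#' @param origin optional geodetic anchor `c(lat, lon, ele)`.
#' @return a [geo_trajectory()].
#' @export
read_gpx <- function(path, origin = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://www.topografix.com/GPX/1/1")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  if (length(pts) == 0) stop("no trkpt elements found")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./g:ele", ns)))
  tme <- xml2::xml_text(xml2::xml_find_first(pts, "./g:time", ns))
  tt <- as.POSIXct(tme, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
  if (anyNA(tt)) stop("trkpt times missing or not ISO-8601 UTC")
  enu <- to_local_frame(lat, lon, ele, origin = origin)
  out <- geo_trajectory(as.numeric(tt) - as.numeric(tt[1]),
                        enu[, 1], enu[, 2], enu[, 3])
  attr(out, "origin") <- attr(enu, "origin")
  out
}

#' @rdname read_gpx
#' @param traj a [geo_trajectory()] with an `origin` attribute (geodetic
#'   anchor) for the inverse conversion.
#' @param start_time POSIXct epoch of the first sample.
#' @export
write_gpx <- function(traj, path, origin = attr(traj, "origin"),
                      start_time = as.POSIXct("2018-10-01 10:00:00", tz = "UTC")) {
  if (is.null(origin)) stop("origin (geodetic anchor) required to write GPX")
  geo <- from_local_frame(as.matrix(traj[, c("x", "y", "z")]), origin)
  times <- format(start_time + traj$time, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
  pts <- sprintf(
    '<trkpt lat="%.8f" lon="%.8f"><ele>%.3f</ele><time>%s</time></trkpt>',
    geo$lat_deg, geo$lon_deg, geo$ele_m, times)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="skipower" xmlns="http://www.topografix.com/GPX/1/1">',
    "<trk><trkseg>", pts, "</trkseg></trk>", "</gpx>"), path)
}

#' Write a 1 Hz kinematic series to CSV
#'
#' @param kin a `kinematic_series`.
#' @param path output path.
#' @export
write_kinematics_csv <- function(kin, path) {
  utils::write.csv(data.frame(
    time_s = kin$time, x_m = kin$x, y_m = kin$y, z_m = kin$z,
    vx = kin$vx, vy = kin$vy, vz = kin$vz, speed = kin$speed,
    accel_along = kin$accel_along, incline_rad = kin$incline,
    curv_x = kin$curv_x, curv_y = kin$curv_y, curv_z = kin$curv_z),
    path, row.names = FALSE, quote = FALSE)
}

#' Write a power series to CSV
#'
#' @param series a `power_series`.
#' @param path output path.
#' @export
write_power_csv <- function(series, path) {
  utils::write.csv(data.frame(
    time_s = series$time, s_m = series$s, lap = series$lap,
    P_prop_wkg = series$P_prop, F_prop_nkg = series$F_prop,
    P_kinetic = series$P_kinetic, P_potential = series$P_potential,
    P_drag = series$P_drag, P_roll = series$P_roll,
    tuck = series$tuck),
    path, row.names = FALSE, quote = FALSE)
}

#' Write a race summary (and optional regression) to JSON
#'
#' @param summary a `race_summary`.
#' @param path output path.
#' @param regression optional output of [fit_power_regression()].
#' @export
write_summary_json <- function(summary, path, regression = NULL) {
  x <- list(mean_wkg = summary$mean_wkg,
            active_mean_wkg = summary$active_mean_wkg,
            peak_wkg = summary$peak_wkg,
            tuck_fraction = summary$tuck_fraction)
  if (!is.null(regression)) {
    x$slope_v <- regression$slope_v
    x$slope_vdot <- regression$slope_vdot
    x$intercept <- regression$intercept
    x$r2 <- regression$r_squared
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}

#' Read a run configuration (YAML)
#'
#' A single structured file holding the athlete, environment, drag-model,
#' Monte Carlo, and simulator sub-configurations plus file paths and the
#' seed. Validation reports every missing required field by name.
#'
#' @param path YAML file.
#' @return a named list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("athlete", "seed")
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0) {
    stop(sprintf("config validation failed; missing field(s): %s",
                 paste(missing, collapse = ", ")))
  }
  amiss <- setdiff(c("mass_kg"), names(cfg$athlete))
  if (length(amiss) > 0) {
    stop(sprintf("config validation failed; missing athlete field(s): %s",
                 paste(amiss, collapse = ", ")))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Build model objects from a run configuration
#'
#' @param cfg a `run_config`.
#' @return list with `athlete`, `env`, `params`, `policy`, `course`,
#'   `noise`, `mc` objects with config overrides applied.
#' @export
config_models <- function(cfg) {
  pick <- function(lst, fn) do.call(fn, lst[intersect(names(lst), names(formals(fn)))])
  list(
    athlete = pick(cfg$athlete %||% list(), athlete_model),
    env = pick(cfg$environment %||% list(), environment_record),
    params = pick(cfg$drag_model %||% list(), drag_model_params),
    policy = pick(cfg$policy %||% list(), power_policy),
    course = pick(utils::modifyList(list(seed = cfg$seed), cfg$course %||% list()),
                  course_spec),
    noise = pick(utils::modifyList(list(seed = cfg$seed), cfg$noise %||% list()),
                 sensor_noise_spec),
    mc = pick(utils::modifyList(list(seed = cfg$seed), cfg$monte_carlo %||% list()),
              monte_carlo_spec))
}
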