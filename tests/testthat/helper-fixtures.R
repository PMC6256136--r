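# Shared fixtures, all generated in code. Heavy objects (the default
# three-lap simulated race and its processed analysis) are built once per
# test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_athlete <- function() athlete_model()
default_env <- function() environment_record(wind10m_ms = 3.5, wind_dir_deg = 30)
default_params <- function() drag_model_params()

zero_noise <- function(seed = 7) {
  sensor_noise_spec(gnss_h_sd = 0, gnss_v_sd = 0, ref_sd = 0,
                    accel_sd = 0, gyro_sd = 0, seed = seed)
}

default_course <- function() memo("course", function() {
  generate_course(course_spec())
})

# small single-lap course for cheap pipeline tests
small_course <- function() memo("small_course", function() {
  generate_course(course_spec(lap_length = 1200, laps = 1, height_diff = 14,
                              total_climb = 45, seed = 3))
})

small_race <- function() memo("small_race", function() {
  simulate_race(small_course(), default_athlete(), power_policy(),
                default_env(), default_params(), laps = 1)
})

small_sensors <- function() memo("small_sensors", function() {
  synthesize_sensors(small_race(), small_course(), zero_noise())
})

full_race <- function() memo("full_race", function() {
  simulate_race(default_course(), default_athlete(), power_policy(),
                default_env(), default_params(), laps = 3)
})

full_analysis <- function() memo("full_analysis", function() {
  sens <- synthesize_sensors(full_race(), default_course(), zero_noise())
  process_race(sens$gnss, sens$reference, sens$imu_torso, sens$imu_thigh,
               athlete = default_athlete(), env = default_env(),
               params = default_params())
})

# straight, flat, constant-speed scenario (speed m/s, duration s)
flat_scenario <- function(speed = 6, duration = 120) {
  tm <- seq(0, duration, 0.1)
  n <- length(tm)
  gnss <- geo_trajectory(tm, speed * tm, rep(0, n), rep(0, n))
  smax <- ceiling(speed * duration) + 50
  ref <- reference_track(seq(0, smax), seq(0, smax), rep(0, smax + 1),
                         rep(0, smax + 1))
  process_race(gnss, ref, athlete = default_athlete(),
               env = environment_record(), params = default_params(),
               area_model = "allometric")
}

# interpolate truth channels onto a time grid
truth_at <- function(truth, what, times) {
  stats::approx(truth$time, truth[[what]], xout = times)$y
}
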