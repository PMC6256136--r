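# skipower

Continuous measurement of the propulsive power a cross-country skier
generates during a (roller-)ski race, from small body-worn sensors: a 10 Hz
GNSS receiver on the torso, two 100 Hz IMUs (torso and thigh), a precisely
surveyed reference trajectory of the course, and hourly weather records.
The package is aimed at sports scientists and performance analysts who want
per-second work-rate estimates — and honest error bars on them — without
instrumented poles, force plates, or a metabolic cart.

## The model

The skier and equipment are a point mass `m`. Propulsive power is whatever
changes mechanical energy or is dissipated to the environment:

    P_prop = dE_mech/dt + dW_env/dt = (m v̇ − F_g − F_d − F_f) · v
    F_prop = P_prop / |v|

with aerodynamic drag `F_d = −½ ρ |v_f|² A·C_D(Re) v̂_f` (posture-dependent
frontal area `A`, Reynolds-dependent drag coefficient `C_D`, velocity
relative to the air `v_f`) and rolling resistance
`Ẇ_f = C_rr |N_g + F_c| |v|` (centripetal load added vectorially to the
normal load in turns). `P_prop` is defined to be zero in the tuck, detected
when the smoothed squared gyro magnitude of both IMUs drops below
5,000 °²·s⁻². Vertical position comes from map-matching the athlete's
horizontal track onto the surveyed course centerline, because standalone
GNSS height is nowhere near accurate enough for the potential-energy term.

A Monte Carlo layer (2,500 samples) propagates the declared uncertainty of
wind (Rayleigh speed, normal direction), frontal area, drag-coefficient
parameters, and `C_rr` into per-second SDs of `P_prop` and `F_prop`, pooled
into a single accuracy figure; a sensitivity analysis asks whether that
accuracy could discriminate athlete-to-athlete or lap-to-lap differences.

A forward-dynamics simulator (undulating closed course, policy-driven
skier with tuck hysteresis, synthetic GNSS/IMU streams) generates ground
truth so the entire pipeline is testable without field data.

## Worked example

Simulate a short two-lap race, synthesize noise-free sensor streams,
process them back through the full pipeline, and summarize:

```r
library(skipower)

course  <- generate_course(course_spec(lap_length = 1500, laps = 2,
                                       height_diff = 20, total_climb = 62,
                                       seed = 1))
athlete <- athlete_model()                       # 77.1 kg, Crr 0.0225, A0 0.55 m^2
policy  <- power_policy()                        # -0.54 v - 0.71 v̇ + 7.26 W/kg
env     <- environment_record(wind10m_ms = 3.5, wind_dir_deg = 30)
params  <- drag_model_params()

truth <- simulate_race(course, athlete, policy, env, params, laps = 2)
sens  <- synthesize_sensors(truth, course,
                            sensor_noise_spec(gnss_h_sd = 0, gnss_v_sd = 0,
                                              ref_sd = 0, accel_sd = 0,
                                              gyro_sd = 0, seed = 1))
ana <- process_race(sens$gnss, sens$reference, sens$imu_torso,
                    sens$imu_thigh, athlete = athlete, env = env,
                    params = params)
ana
#> <race_analysis> 449 s, 2 lap(s)
#> <race_summary> mean 3.17 W/kg, active mean 4.11 W/kg, peak 5.54 W/kg, tuck 23%

fit_power_regression(ana$power)[c("slope_v", "slope_vdot", "intercept")]
#> $slope_v    [1] -0.55
#> $slope_vdot [1] -0.70
#> $intercept  [1] 7.28

run_monte_carlo(ana, monte_carlo_spec(n_samples = 500, seed = 1,
                                      wind_mean_1m = 1.75,
                                      wind_dir_mean = 30))
#> <monte_carlo_result> 500 samples: pooled SD 0.613 W/kg (P), 0.1055 N/kg (F)
```

Reading the numbers: the race mean (3.17 W/kg) is pulled down by the 23% of
time spent coasting in the tuck, where power is zero by definition; the
active mean (4.11 W/kg) is the work rate while actually propelling. The
refitted regression recovers the policy that drove the simulator
(−0.54 N/kg, −0.71 N·s/kg, 7.26 W/kg) to within a few hundredths — the
pipeline inverts its own physics. The Monte Carlo pooled SD is the
measurement accuracy under the configured error model: ~0.1 N/kg of
propulsive force here, dominated by the wind and frontal-area terms.

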