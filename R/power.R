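# Power-balance inversion: propulsive power and force, race summaries,
# the speed/acceleration power regression and the steady-state speed curve.

#' Power policy (linear power-speed-acceleration model)
#'
#' A linear model of mass-normalized propulsive power,
#' `P(v, vdot) = slope_v * v + slope_vdot * vdot + intercept` (W/kg), with
#' a tuck rule: power is zero while tucked, entered above `tuck_enter` and
#' left below `tuck_exit` (hysteresis). Used both to summarize processed
#' races and to drive the forward simulator. Defaults are the coefficients
#' fitted to the elite-skier cohort: -0.54 N/kg, -0.71 N s/kg, 7.26 W/kg,
#' tuck above ~9 m/s.
#'
#' @param slope_v speed coefficient (N/kg).
#' @param slope_vdot acceleration coefficient (N s/kg).
#' @param intercept intercept (W/kg).
#' @param tuck_enter,tuck_exit tuck hysteresis speeds (m/s).
#' @param floor,ceiling clamps on the commanded power (W/kg).
#' @return a list of class `power_policy`.
#' @export
power_policy <- function(slope_v = -0.54, slope_vdot = -0.71, intercept = 7.26,
                         tuck_enter = 9, tuck_exit = 8, floor = 0,
                         ceiling = Inf) {
  stopifnot(tuck_exit <= tuck_enter, floor <= ceiling)
  structure(list(slope_v = slope_v, slope_vdot = slope_vdot,
                 intercept = intercept, tuck_enter = tuck_enter,
                 tuck_exit = tuck_exit, floor = floor, ceiling = ceiling),
            class = "power_policy")
}

#' Evaluate a power policy
#'
#' @param policy a [power_policy()].
#' @param v speed (m/s).
#' @param vdot along-track acceleration (m/s^2).
#' @param clamp apply the policy's floor/ceiling.
#' @return mass-normalized power (W/kg).
#' @export
predict_policy <- function(policy, v, vdot = 0, clamp = TRUE) {
  p <- policy$slope_v * v + policy$slope_vdot * vdot + policy$intercept
  if (clamp) p <- pmin(pmax(p, policy$floor), policy$ceiling)
  p
}

#' Propulsive power from the power balance
#'
#' Inverts the point-mass power balance at 1 Hz:
#' `P_prop / m = vdot . v + g v_z - (F_d . v) / m + W_f_dot / m`
#' (kinetic rate + potential rate - drag power + rolling dissipation).
#' The raw series is smoothed with a 5 s bidirectional moving average and
#' tuck samples are then set exactly to zero (order configurable). Negative
#' values are retained (braking or measurement error), not clipped.
#'
#' @param kin a `kinematic_series` (see [build_kinematics()]).
#' @param P_drag drag power per kg (W/kg, <= 0), time-aligned with `kin`.
#' @param P_roll rolling dissipation per kg (W/kg, >= 0).
#' @param tuck logical tuck flags, time-aligned.
#' @param smooth_window_s moving-average window (s); 0 disables smoothing.
#' @param zero_tuck `"after"` (default: zero after smoothing, so tuck
#'   samples are exactly zero) or `"before"`.
#' @param speed_floor speed floor (m/s) below which F_prop is flagged.
#' @return data frame of class `power_series`: `time`, `s`, `lap`,
#'   `P_prop`, `F_prop` (per kg), component powers `P_kinetic`,
#'   `P_potential`, `P_drag`, `P_roll`, `tuck`, `speed`, `flag_lowspeed`.
#' @export
propulsive_power <- function(kin, P_drag, P_roll, tuck,
                             smooth_window_s = 5, zero_tuck = c("after", "before"),
                             speed_floor = attr(kin, "speed_floor") %||% 0.5) {
  zero_tuck <- match.arg(zero_tuck)
  n <- nrow(kin)
  if (length(P_drag) != n || length(P_roll) != n || length(tuck) != n) {
    stop("P_drag, P_roll and tuck must be time-aligned with the kinematic series")
  }
  # vdot . v = (vdot . v_hat) |v| = along-track acceleration times speed
  P_kin <- kin$accel_along * kin$speed
  P_pot <- G_ACCEL * kin$vz
  P <- P_kin + P_pot - P_drag + P_roll
  fs <- 1 / stats::median(diff(kin$time))
  if (zero_tuck == "before") P[tuck] <- 0
  if (smooth_window_s > 0) P <- smooth_ma(P, smooth_window_s, fs)
  if (zero_tuck == "after") P[tuck] <- 0
  low <- kin$speed < speed_floor
  F_prop <- ifelse(low, NA_real_, P / kin$speed)
  F_prop[tuck] <- 0
  out <- data.frame(time = kin$time, s = kin$s, lap = kin$lap,
                    P_prop = P, F_prop = F_prop,
                    P_kinetic = P_kin, P_potential = P_pot,
                    P_drag = P_drag, P_roll = P_roll,
                    tuck = tuck, speed = kin$speed,
                    accel_along = kin$accel_along,
                    flag_lowspeed = low)
  attr(out, "smooth_window_s") <- smooth_window_s
  class(out) <- c("power_series", "data.frame")
  out
}

#' Propulsive force from power and speed
#'
#' `F_prop = P_prop / |v|`; below the speed floor the division is
#' unreliable and the sample is flagged missing (NA). Sign is preserved.
#'
#' @param P_prop mass-normalized power (W/kg).
#' @param speed speed (m/s).
#' @param speed_floor floor (m/s).
#' @return force per kg (N/kg).
#' @export
propulsive_force <- function(P_prop, speed, speed_floor = 0.5) {
  ifelse(speed < speed_floor, NA_real_, P_prop / speed)
}

#' Regression of propulsive power on speed and acceleration
#'
#' Ordinary least squares of P_prop on skiing speed and along-track
#' acceleration with intercept, over non-tuck samples only (the tuck
#' samples are zero by definition and would bias the fit). Because the
#' power series carries the 5 s zero-phase moving average, the predictors
#' are smoothed with the same window by default; regressing a filtered
#' response on unfiltered predictors would attenuate the acceleration
#' coefficient and misattribute its contribution to speed. For the same
#' reason, non-tuck samples within half a smoothing window of a tuck
#' transition are dropped: there the smoothed power mixes active
#' propulsion with the tucked zeros and reflects the filter, not the
#' athlete's power-speed relationship.
#'
#' @param series a `power_series`.
#' @param min_samples minimum number of non-tuck samples.
#' @param smooth_predictors_s smoothing window (s) applied to the
#'   predictors; defaults to the window the power series was smoothed
#'   with. 0 disables.
#' @param transition_margin_s exclusion margin (s) around tuck
#'   transitions; defaults to half the smoothing window plus a sample.
#' @return list with `slope_v` (N/kg), `slope_vdot` (N s/kg), `intercept`
#'   (W/kg), `r_squared`, `n`, and the `lm` fit.
#' @export
fit_power_regression <- function(series, min_samples = 30,
                                 smooth_predictors_s =
                                   attr(series, "smooth_window_s") %||% 0,
                                 transition_margin_s =
                                   (smooth_predictors_s + 1) / 2) {
  d <- series
  fs <- 1 / stats::median(diff(series$time))
  if (smooth_predictors_s > 0) {
    d$speed <- smooth_ma(d$speed, smooth_predictors_s, fs)
    d$accel_along <- smooth_ma(d$accel_along, smooth_predictors_s, fs)
  }
  keep <- !d$tuck & !d$flag_lowspeed
  if (transition_margin_s > 0 && any(d$tuck) && !all(d$tuck)) {
    m <- round(transition_margin_s * fs)
    for (e in which(diff(d$tuck) != 0)) {
      keep[max(1, e - m + 1):min(length(keep), e + m)] <- FALSE
    }
  }
  d <- d[keep, ]
  if (nrow(d) < min_samples) {
    stop(sprintf("only %d non-tuck samples; need >= %d", nrow(d), min_samples))
  }
  fit <- stats::lm(P_prop ~ speed + accel_along, data = d)
  co <- stats::coef(fit)
  list(slope_v = unname(co["speed"]), slope_vdot = unname(co["accel_along"]),
       intercept = unname(co["(Intercept)"]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = nrow(d), fit = fit)
}

#' Steady-state speed on a constant grade under a linear power policy
#'
#' Setting vdot = 0 in the power balance and substituting the linear
#' policy P(v) gives the cubic
#' `0.5 rho ACD v^3 + (m g (sin th + Crr cos th) - m slope_v) v
#'  - m intercept = 0`,
#' whose positive real root is the equilibrium speed. When that root
#' exceeds the policy's tuck-entry speed the athlete coasts instead, and
#' the zero-power equilibrium (drag + rolling balancing gravity on a
#' descent) applies.
#'
#' @param inclination course inclination (rad), vectorized.
#' @param policy a [power_policy()]; `NULL` forces the zero-power branch.
#' @param mass system mass (kg).
#' @param ACD drag area (m^2).
#' @param crr rolling-resistance coefficient.
#' @param rho air density (kg m^-3).
#' @return steady-state speed (m/s); NA where no positive equilibrium
#'   exists.
#' @export
steady_state_speed <- function(inclination, policy, mass, ACD, crr, rho) {
  one <- function(th) {
    grav <- mass * G_ACCEL * (sin(th) + crr * cos(th))
    k <- 0.5 * rho * ACD
    root_zero <- if (grav < 0) sqrt(-grav / k) else NA_real_
    if (is.null(policy)) return(root_zero)
    # 0.5 rho ACD v^3 + (grav - m a) v - m c = 0 (a = slope_v, c = intercept)
    rts <- polyroot(c(-mass * policy$intercept, grav - mass * policy$slope_v, 0, k))
    re <- Re(rts)[abs(Im(rts)) < 1e-8 & Re(rts) > 0]
    if (length(re) == 0) stop("no positive steady-state root; non-physical parameters")
    v <- min(re)
    # above the tuck-entry speed the athlete coasts instead -- but only
    # when the zero-power equilibrium itself sustains the tuck
    if (v > policy$tuck_enter && !is.na(root_zero) &&
        root_zero > policy$tuck_exit) root_zero else v
  }
  vapply(inclination, one, numeric(1))
}

#' Race-level summary of a power series
#'
#' Mean over the race, active mean (tuck samples omitted), peak of the
#' smoothed series, tuck fraction and per-lap means.
#'
#' @param series a `power_series`.
#' @return list of class `race_summary` with `mean_wkg`,
#'   `active_mean_wkg` (NA when every sample is tucked), `peak_wkg`,
#'   `tuck_fraction`, `lap_mean_wkg`.
#' @export
summarize_race <- function(series) {
  active <- series$P_prop[!series$tuck]
  structure(list(
    mean_wkg = mean(series$P_prop),
    active_mean_wkg = if (length(active) == 0) NA_real_ else mean(active),
    peak_wkg = max(series$P_prop),
    tuck_fraction = mean(series$tuck),
    lap_mean_wkg = tapply(series$P_prop, series$lap, mean)),
    class = "race_summary")
}

#' @export
print.race_summary <- function(x, ...) {
  cat(sprintf("<race_summary> mean %.2f W/kg, active mean %.2f W/kg, peak %.2f W/kg, tuck %.0f%%\n",
              x$mean_wkg, x$active_mean_wkg, x$peak_wkg, 100 * x$tuck_fraction))
  invisible(x)
}

#' Measurement-error model for propulsive force and power
#'
#' Evaluates a linear error model of the propulsive-force standard
#' deviation over speed, `SD(F_prop) = slope * v + intercept`, and the
#' implied power error `SD(P_prop) = SD(F_prop) * v` (since
#' `P_prop = F_prop v`, so the error grows curvilinearly with speed).
#' Defaults are the coefficients fitted to the Monte Carlo accuracy study
#' of the elite-skier cohort.
#'
#' @param v speed (m/s), vectorized.
#' @param slope error-regression slope (N s m^-1 kg^-1).
#' @param intercept error-regression intercept (N/kg).
#' @return data frame with `v`, `sd_F` (N/kg), `sd_P` (W/kg).
#' @export
power_error_model <- function(v, slope = 2.8e-3, intercept = 3.9e-2) {
  sd_F <- slope * v + intercept
  data.frame(v = v, sd_F = sd_F, sd_P = sd_F * v)
}

#' Metabolic power from propulsive power and gross efficiency
#'
#' @param p_prop_wkg propulsive power (W/kg).
#' @param gross_efficiency mechanical / metabolic power ratio.
#' @return metabolic power (W/kg).
#' @export
metabolic_power <- function(p_prop_wkg, gross_efficiency = 0.164) {
  stopifnot(gross_efficiency > 0, gross_efficiency <= 1)
  p_prop_wkg / gross_efficiency
}

#' Oxygen demand from metabolic power
#'
#' Converts metabolic power to oxygen uptake with the energy equivalent of
#' oxygen (about 20.9 kJ per liter O2).
#'
#' @param metab_wkg metabolic power (W/kg).
#' @param kj_per_l energy equivalent of oxygen (kJ/L).
#' @return oxygen uptake (mL kg^-1 min^-1).
#' @export
oxygen_uptake <- function(metab_wkg, kj_per_l = 20.9) {
  metab_wkg * 60 / kj_per_l
}
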