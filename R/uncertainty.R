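# Monte Carlo propagation of the input-error distributions into the
# propulsive power/force estimates, and the sensitivity (discriminability)
# analysis against inter-athlete and lap-to-lap variability.

#' Monte Carlo specification
#'
#' Distributions of the perturbed inputs: wind speed is Rayleigh with
#' expectation equal to the hourly mean at athlete height (scale =
#' mean * sqrt(2/pi)); wind direction is normal; the frontal-area residual
#' is a zero-mean normal offset; the drag-coefficient logistic parameters
#' are multivariate normal; the reference drag coefficient and the rolling
#' resistance coefficient are normal. Setting an SD (or the wind mean) to
#' zero disables that perturbation.
#'
#' @param n_samples number of Monte Carlo samples (>= 2).
#' @param seed master seed; each sample uses a derived substream so results
#'   do not depend on evaluation order.
#' @param wind_mean_1m Rayleigh expectation of wind speed at athlete height
#'   (m/s).
#' @param wind_dir_mean,wind_dir_sd wind-direction normal (deg).
#' @param area_resid_sd frontal-area model residual SD (m^2). The default
#'   0.02 m^2 is a synthetic stand-in: the residual SD of the area fit is
#'   not published.
#' @param alpha_mean,alpha_cov drag-coefficient parameter distribution;
#'   `NULL` uses the model parameters with a diagonal covariance built from
#'   the published 95% confidence intervals, `(CI half-width / 1.96)^2`.
#' @param cd_mean,cd_sd reference drag-coefficient normal.
#' @param crr_mean,crr_sd rolling-resistance normal; `NULL` uses the
#'   athlete model values.
#' @param area_redraw draw the area residual i.i.d. per time step instead
#'   of once per sample (default FALSE: model error persists within a
#'   sample).
#' @return list of class `monte_carlo_spec`.
#' @export
monte_carlo_spec <- function(n_samples = 2500, seed = 1,
                             wind_mean_1m = 0, wind_dir_mean = 0,
                             wind_dir_sd = 25, area_resid_sd = 0.02,
                             alpha_mean = NULL, alpha_cov = NULL,
                             cd_mean = 0.872, cd_sd = 0.079,
                             crr_mean = NULL, crr_sd = NULL,
                             area_redraw = FALSE) {
  stopifnot(n_samples >= 2, wind_dir_sd >= 0, area_resid_sd >= 0, cd_sd >= 0)
  structure(list(n_samples = n_samples, seed = seed,
                 wind_mean_1m = wind_mean_1m, wind_dir_mean = wind_dir_mean,
                 wind_dir_sd = wind_dir_sd, area_resid_sd = area_resid_sd,
                 alpha_mean = alpha_mean, alpha_cov = alpha_cov,
                 cd_mean = cd_mean, cd_sd = cd_sd,
                 crr_mean = crr_mean, crr_sd = crr_sd,
                 area_redraw = area_redraw),
            class = "monte_carlo_spec")
}

# resolve the NULL-able fields of a spec against athlete/params
resolve_mc_spec <- function(spec, athlete, params) {
  spec$alpha_mean <- spec$alpha_mean %||% params$alpha
  if (is.null(spec$alpha_cov)) {
    hw <- (params$alpha_ci[, 2] - params$alpha_ci[, 1]) / 2
    spec$alpha_cov <- diag((hw / 1.96)^2)
  }
  ev <- eigen(spec$alpha_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("alpha_cov is not positive semi-definite")
  spec$crr_mean <- spec$crr_mean %||% athlete$crr
  spec$crr_sd <- spec$crr_sd %||% athlete$crr_sd
  spec
}

#' Draw one perturbed parameter set
#'
#' @param spec a resolved [monte_carlo_spec()] (all fields non-NULL).
#' @return list with `wind_speed`, `wind_dir`, `area_offset`, `alpha`,
#'   `cd_schenau`, `crr`.
#' @export
sample_perturbation <- function(spec) {
  rayleigh_scale <- spec$wind_mean_1m * sqrt(2 / pi)
  wind_speed <- if (rayleigh_scale > 0) {
    rayleigh_scale * sqrt(-2 * log(stats::runif(1)))
  } else 0
  list(
    wind_speed = wind_speed,
    wind_dir = stats::rnorm(1, spec$wind_dir_mean, spec$wind_dir_sd),
    area_offset = stats::rnorm(1, 0, spec$area_resid_sd),
    alpha = as.numeric(MASS::mvrnorm(1, spec$alpha_mean, spec$alpha_cov)),
    cd_schenau = stats::rnorm(1, spec$cd_mean, spec$cd_sd),
    crr = stats::rnorm(1, spec$crr_mean, spec$crr_sd))
}

#' Monte Carlo uncertainty propagation for a processed race
#'
#' Re-evaluates the force models and the power-balance inversion for
#' `n_samples` perturbed parameter sets on the fixed kinematics (the
#' perturbed inputs do not affect the trajectory stage), accumulating the
#' per-time-step mean and SD of P_prop and F_prop. The method's accuracy
#' is the pooled SD (root-mean-square of per-step SDs over non-tuck
#' samples), and the error regression fits SD(F_prop) against speed over
#' non-tuck samples.
#'
#' @param analysis a `race_analysis` from [process_race()].
#' @param spec a [monte_carlo_spec()].
#' @return list of class `monte_carlo_result`: per-step `mean_P`, `sd_P`,
#'   `mean_F`, `sd_F`; `pooled_sd_P`, `pooled_sd_F`; `error_regression`
#'   (slope, intercept of sd_F ~ speed); `n_samples`, `n_rejected`.
#' @export
run_monte_carlo <- function(analysis, spec = monte_carlo_spec()) {
  kin <- analysis$kinematics
  tuck <- analysis$power$tuck
  spec <- resolve_mc_spec(spec, analysis$athlete, analysis$params)
  seeds <- derive_seeds(spec$seed, spec$n_samples)
  n <- nrow(kin)
  sum_P <- ss_P <- sum_F <- ss_F <- numeric(n)
  n_rej <- 0L
  fs <- 1 / stats::median(diff(kin$time))
  wind_height_factor <- 1  # spec$wind_mean_1m is already at athlete height
  for (k in seq_len(spec$n_samples)) {
    pert <- with_seed(seeds[k], sample_perturbation(spec))
    params_k <- analysis$params
    params_k$alpha <- pert$alpha
    wvec <- wind_vector(pert$wind_speed * wind_height_factor, pert$wind_dir)
    offset <- if (spec$area_redraw) {
      with_seed(seeds[k] + 1L, stats::rnorm(n, 0, spec$area_resid_sd))
    } else pert$area_offset
    rp <- compute_resistive_powers(kin, analysis$area, analysis$athlete,
                                   analysis$atm, wvec, params_k,
                                   crr = pert$crr,
                                   cd_schenau = pert$cd_schenau,
                                   area_offset = offset)
    P <- kin$accel_along * kin$speed + G_ACCEL * kin$vz - rp$P_drag + rp$P_roll
    P <- smooth_ma(P, 5, fs)
    P[tuck] <- 0
    Fp <- ifelse(kin$speed < 0.5, NA_real_, P / kin$speed)
    Fp[tuck] <- 0
    if (any(!is.finite(P))) {
      n_rej <- n_rej + 1L
      next
    }
    sum_P <- sum_P + P; ss_P <- ss_P + P^2
    ok <- !is.na(Fp)
    sum_F[ok] <- sum_F[ok] + Fp[ok]; ss_F[ok] <- ss_F[ok] + Fp[ok]^2
  }
  if (n_rej > 0.01 * spec$n_samples) {
    stop(sprintf("%d of %d Monte Carlo samples produced non-finite power",
                 n_rej, spec$n_samples))
  }
  m <- spec$n_samples - n_rej
  mean_P <- sum_P / m
  sd_P <- sqrt(pmax(ss_P / m - mean_P^2, 0) * m / max(m - 1, 1))
  mean_F <- sum_F / m
  sd_F <- sqrt(pmax(ss_F / m - mean_F^2, 0) * m / max(m - 1, 1))
  active <- !tuck
  er <- if (sum(active) >= 3 && stats::sd(kin$speed[active]) > 1e-9) {
    fit <- stats::lm(sd_F[active] ~ kin$speed[active])
    c(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
  } else c(slope = NA_real_, intercept = NA_real_)
  structure(list(
    time = kin$time, speed = kin$speed, tuck = tuck,
    mean_P = mean_P, sd_P = sd_P, mean_F = mean_F, sd_F = sd_F,
    pooled_sd_P = sqrt(mean(sd_P[active]^2)),
    pooled_sd_F = sqrt(mean(sd_F[active]^2)),
    error_regression = er,
    n_samples = spec$n_samples, n_rejected = n_rej),
    class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf("<monte_carlo_result> %d samples: pooled SD %.3f W/kg (P), %.4f N/kg (F)\n",
              x$n_samples, x$pooled_sd_P, x$pooled_sd_F))
  invisible(x)
}

#' Sensitivity of the method against cohort variability
#'
#' Compares the measurement accuracy (pooled Monte Carlo SD of F_prop)
#' with the inter-athlete (or intra-athlete lap-to-lap) SD of F_prop
#' evaluated at common integer-meter course positions, tuck samples
#' excluded. The method can discriminate differences when the cohort SD
#' exceeds the accuracy for more than 90% of positions.
#'
#' @param f_prop_matrix numeric matrix, rows = course positions, columns =
#'   athletes (inter) or laps (intra); NA marks tucked/absent samples.
#' @param accuracy measurement accuracy (N/kg).
#' @param min_units minimum columns contributing per row.
#' @return list of class `sensitivity_result`: per-position `sd`,
#'   `fraction_above`, `verdict` (90% rule), and `eccdf` (a function).
#' @export
sensitivity_eccdf <- function(f_prop_matrix, accuracy, min_units = 2) {
  f_prop_matrix <- as.matrix(f_prop_matrix)
  if (ncol(f_prop_matrix) < 2) {
    stop("need at least 2 athletes (or laps) to form a variability SD")
  }
  n_ok <- rowSums(!is.na(f_prop_matrix))
  sds <- apply(f_prop_matrix, 1, stats::sd, na.rm = TRUE)
  sds[n_ok < min_units] <- NA
  valid <- sds[!is.na(sds)]
  frac <- mean(valid > accuracy)
  structure(list(sd = sds, accuracy = accuracy, fraction_above = frac,
                 verdict = frac > 0.9,
                 eccdf = function(x) vapply(x, function(xx) mean(valid > xx),
                                            numeric(1))),
            class = "sensitivity_result")
}
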