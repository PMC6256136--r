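# Rolling resistance: normal loading (gravity + centripetal) and the
# dissipative work rate of the roller-ski wheels.

#' Surface-normal gravity load
#'
#' `|N_g| = m g cos(inclination)`: the component of gravity perpendicular
#' to the rolling surface, which is assumed level in the mediolateral
#' direction.
#'
#' @param mass system mass (kg).
#' @param inclination surface inclination (rad), |inclination| < pi/2.
#' @return normal force magnitude (N), vectorized over `inclination`.
#' @export
normal_force <- function(mass, inclination) {
  stopifnot(all(abs(inclination) < pi / 2))
  mass * G_ACCEL * cos(inclination)
}

#' Centripetal force from track curvature
#'
#' `F_c = m |v|^2 K` with K the track curvature vector (see
#' [curvature()]); zero on straight segments.
#'
#' @param mass system mass (kg).
#' @param v n x 3 velocity (m/s).
#' @param K n x 3 curvature (1/m).
#' @return n x 3 force matrix (N).
#' @export
centripetal_force <- function(mass, v, K) {
  v <- as_matrix3(v); K <- as_matrix3(K)
  mass * row_norm(v)^2 * K
}

# unit surface-normal in the vertical plane of motion: the vertical axis
# with its along-velocity component removed
surface_normal <- function(v) {
  v <- as_matrix3(v)
  sp2 <- pmax(rowSums(v * v), 1e-12)
  n <- cbind(-v[, 1] * v[, 3] / sp2, -v[, 2] * v[, 3] / sp2, 1 - v[, 3]^2 / sp2)
  n / pmax(row_norm(n), 1e-12)
}

#' Rolling-resistance work rate
#'
#' `W_f_dot = Crr * |N_g + F_c| * |v|`: centripetal shear forces during
#' turns add vectorially to the gravity normal load before the magnitude
#' is taken, so cornering at speed strictly increases rolling dissipation.
#' Always >= 0 (dissipative); zero only at standstill or Crr = 0.
#'
#' @param crr coefficient of rolling resistance.
#' @param N_g normal force magnitude (N), from [normal_force()].
#' @param F_c n x 3 centripetal force (N), from [centripetal_force()].
#' @param v n x 3 velocity (m/s).
#' @return work rate (W), vectorized.
#' @export
rolling_power <- function(crr, N_g, F_c, v) {
  v <- as_matrix3(v); F_c <- as_matrix3(F_c)
  n_hat <- surface_normal(v)
  total <- n_hat * N_g + F_c
  crr * row_norm(total) * row_norm(v)
}
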