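#' @keywords internal
"_PACKAGE"

# gravitational acceleration used throughout (m s^-2)
G_ACCEL <- 9.81

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-pass centered moving average with shrinking edge windows
#'
#' Each output sample is the mean of the input over a centered window of
#' `n` samples; near the series edges the window shrinks to the available
#' samples so that constant signals are reproduced exactly everywhere.
#'
#' @param x numeric vector.
#' @param n odd window length in samples (>= 3).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average_pass <- function(x, n) {
  stopifnot(is.numeric(x), n >= 3)
  if (n %% 2 == 0) n <- n + 1
  half <- (n - 1) / 2
  m <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(m) - half, 1)
  hi <- pmin(seq_len(m) + half, m)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Bidirectional (zero-phase) moving average
#'
#' Applies the centered boxcar twice, which is equivalent to convolving the
#' signal with a triangular kernel (the convolution of two boxcars), the
#' impulse response of a forward-then-backward moving-average filter. The
#' window is specified in seconds and converted to an odd sample count.
#'
#' @param x numeric vector, uniformly sampled.
#' @param window_s window length in seconds of each boxcar pass.
#' @param fs sampling frequency in Hz.
#' @param passes number of boxcar passes (2 = bidirectional, the default).
#' @return smoothed numeric vector, same length as `x`.
#' @export
smooth_ma <- function(x, window_s, fs, passes = 2) {
  n <- 2 * floor(window_s * fs / 2) + 1
  if (n < 3) stop("moving-average window shorter than 3 samples")
  for (i in seq_len(passes)) x <- moving_average_pass(x, n)
  x
}

#' Canonical four-limit logistic
#'
#' f(x) = high - amplitude / (1 + exp(-(x - mid) / width)). Used by both the
#' allometric frontal-area model and the Reynolds-dependent drag-coefficient
#' model, which share this sigmoid shape with different axes.
#'
#' @param x evaluation points.
#' @param high low-x plateau value.
#' @param amplitude drop between the low-x and high-x plateaus.
#' @param mid transition midpoint (same units as `x`).
#' @param width transition width (same units as `x`); larger = more gradual.
#' @return numeric vector.
#' @export
logistic_transition <- function(x, high, amplitude, mid, width) {
  high - amplitude / (1 + exp(-(x - mid) / width))
}

# row-wise Euclidean norm of an n x 3 matrix
row_norm <- function(m) sqrt(rowSums(m * m))

# 3D cross product for n x 3 matrices (row-wise)
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_matrix3 <- function(v) {
  if (is.null(dim(v))) matrix(v, ncol = 3) else as.matrix(v)
}

# draw n sub-seeds below 2^31 from a master seed, so that each Monte Carlo
# sample (or sensor stream) has its own reproducible substream independent
# of evaluation order
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
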