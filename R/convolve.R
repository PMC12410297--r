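#' Convolution with a decaying exponential kernel
#'
#' Computes `(f (*) exp(-theta t))(t_i) = int_0^{t_i} f(s) exp(-theta (t_i - s)) ds`
#' for a function sampled on a uniform grid, treating `f` as piecewise linear
#' between samples. The recursion over grid steps is exact for piecewise-linear
#' inputs and is evaluated at C speed via [stats::filter()]. With `theta = 0`
#' the running (trapezoidal) integral is returned. This kernel is the basis
#' function of the reference-tissue models and of the one-tissue reference
#' region simulator.
#'
#' @param values numeric vector of samples on a uniform grid starting at t = 0.
#' @param theta decay constant of the kernel (1/min), `>= 0`.
#' @param dt grid step (minutes). Supply either `dt` or `times`.
#' @param times optional grid times; must be uniform (checked), starting at 0.
#' @return numeric vector of the convolution at the same grid points.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' y <- convolve_exp(rep(1, length(t)), theta = 0.3, dt = 0.01)
#' max(abs(y - (1 - exp(-0.3 * t)) / 0.3))  # ~1e-16: closed form
#' @export
convolve_exp <- function(values, theta, dt = NULL, times = NULL) {
  stopifnot(is.numeric(values), is.numeric(theta), length(theta) == 1L, theta >= 0)
  if (is.null(dt)) {
    if (is.null(times)) stop("supply either 'dt' or 'times'")
    d <- diff(times)
    if (length(d) == 0L) stop("grid needs at least two points")
    if (max(abs(d - d[1])) > 1e-9 * max(d[1], 1)) stop("grid is not uniform")
    dt <- d[1]
  }
  stopifnot(length(dt) == 1L, dt > 0)
  n <- length(values)
  if (n < 2L) return(rep(0, n))
  f0 <- values[-n]
  f1 <- values[-1L]
  if (theta == 0) {
    return(c(0, cumsum(dt * (f0 + f1) / 2)))
  }
  a <- exp(-theta * dt)
  e0 <- (1 - a) / theta
  e1 <- (1 - (1 + theta * dt) * a) / theta^2
  inc <- f1 * (e0 - e1 / dt) + f0 * (e1 / dt)
  c(0, as.numeric(stats::filter(inc, a, method = "recursive")))
}

# Cumulative trapezoidal integral on a uniform grid (vector same length).
cum_trapz <- function(values, dt) convolve_exp(values, theta = 0, dt = dt)

# Uniform fine grid covering a frame schedule (t = 0 .. end of last frame).
fine_times <- function(schedule, dt = 0.01) {
  end <- max(schedule$frame_start + schedule$frame_duration)
  m <- round(end / dt)
  if (abs(end / dt - m) > 1e-6) stop("schedule end is not a multiple of the fine grid step")
  dt * (0:m)
}

# Index of time t on the fine grid (1-based); t must land on a grid point.
grid_index <- function(t, dt, n) {
  i <- t / dt
  j <- round(i)
  if (any(abs(i - j) > 1e-6)) stop("frame boundary does not align with the fine grid")
  if (any(j < 0) || any(j + 1 > n)) stop("frame boundary outside the fine grid")
  as.integer(j) + 1L
}

# Average of a fine-grid curve over each frame (trapezoidal mean).
frame_average <- function(values, dt, schedule) {
  ct <- cum_trapz(values, dt)
  a <- grid_index(schedule$frame_start, dt, length(values))
  b <- grid_index(schedule$frame_start + schedule$frame_duration, dt, length(values))
  (ct[b] - ct[a]) / schedule$frame_duration
}

# Reconstruct a fine-grid curve from a framed TAC. Starts from linear
# interpolation through (0, 0) and the frame mid-times, then applies a few
# fixed-point sweeps nudging the mid-time knots so the reconstruction's frame
# averages match the framed data (mid-time interpolation alone biases frames
# where the curve is convex, i.e. around the uptake peak).
tac_interpolate <- function(x, dt = 0.01, refine = 3L) {
  sched <- tac_schedule(x)
  tt <- fine_times(sched, dt)
  mids <- tac_midtimes(x)
  vals <- x$activity
  knots_t <- c(0, mids, max(tt))
  build <- function(v) {
    stats::approx(knots_t, c(0, v, v[length(v)]), xout = tt, rule = 2)$y
  }
  fine <- build(vals)
  v <- vals
  for (i in seq_len(refine)) {
    fa <- frame_average(fine, dt, sched)
    v <- v + (vals - fa)
    fine <- build(v)
  }
  fine
}

# Fine-grid representation of a TAC: use the exact curve attached by the
# simulators when present, otherwise reconstruct from the frames.
tac_fine <- function(x, dt = 0.01, use_attr = TRUE) {
  f <- attr(x, "fine")
  if (use_attr && !is.null(f) && isTRUE(abs(f$dt - dt) < 1e-12)) return(f$values)
  tac_interpolate(x, dt = dt)
}
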