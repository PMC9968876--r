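#' Filter specifications
#'
#' A `filter_spec` bundles the order and cutoff of a low-pass Butterworth
#' filter. The pipeline uses two of them: a 4th-order, 35 Hz filter for
#' inertial channels and a 2nd-order, 20 Hz filter for insole force
#' channels, both applied with zero lag (forward-backward).
#'
#' @param order Filter order of the underlying one-pass design (2 or 4).
#' @param cutoff_hz Cutoff frequency in Hz; must lie below the Nyquist
#'   frequency of the series the spec is applied to.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order, cutoff_hz) {
  if (!order %in% c(2L, 4L)) stop("filter order must be 2 or 4", call. = FALSE)
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive", call. = FALSE)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "lowpass"),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %d-order lowpass Butterworth, fc = %g Hz (zero-lag)\n",
              x$order, x$cutoff_hz))
  invisible(x)
}

#' Default filter specs for inertial and force channels
#' @rdname filter_spec
#' @export
imu_filter_spec <- function() filter_spec(4L, 35)

#' @rdname filter_spec
#' @export
force_filter_spec <- function() filter_spec(2L, 20)

# expand a monic polynomial from its (complex) roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Low-pass Butterworth coefficients
#'
#' Designs a digital low-pass Butterworth filter by the bilinear transform
#' with frequency prewarping. DC gain is exactly 1.
#'
#' @param order Filter order.
#' @param cutoff_hz Cutoff (-3 dB) frequency, Hz.
#' @param rate Sampling rate, Hz.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_lowpass <- function(order, cutoff_hz, rate) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("cutoff must lie in (0, rate/2)", call. = FALSE)
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * rate
  wc <- fs2 * tan(pi * cutoff_hz / rate)
  p <- p * wc
  pz <- (fs2 + p) / (fs2 - p)                 # bilinear transform
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))  # zeros at Nyquist
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# steady-state filter state for a unit step input (the lfilter_zi
# construction), used so forward-backward filtering is insensitive to edges
filter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, n + 1 - length(b)))
  a <- c(a, rep(0, n + 1 - length(a)))
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[2:(n + 1)]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  solve(diag(n) - t(comp), b[2:(n + 1)] - a[2:(n + 1)] * b[1])
}

#' Zero-lag (forward-backward) low-pass filtering
#'
#' Applies the Butterworth filter described by `spec` forward and then
#' backward, which cancels the phase response at the cost of squaring the
#' magnitude response (a 4th-order design therefore attenuates like an
#' 8th-order magnitude). Edges are handled by odd reflective padding of
#' length `3 * order` samples.
#'
#' @param series Numeric vector.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate of `series`, Hz.
#' @return Filtered vector, same length as `series`.
#' @export
lowpass_zero_lag <- function(series, spec, rate) {
  stopifnot(inherits(spec, "filter_spec"))
  npad <- 3L * spec$order
  if (length(series) <= npad)
    stop(sprintf("series too short for zero-lag filtering (need > %d samples)",
                 npad), call. = FALSE)
  co <- butter_lowpass(spec$order, spec$cutoff_hz, rate)
  n <- length(series)
  # odd reflection about the end samples, as is standard for filtfilt
  head_pad <- 2 * series[1] - series[(npad + 1):2]
  tail_pad <- 2 * series[n] - series[(n - 1):(n - npad)]
  x <- c(head_pad, series, tail_pad)
  zi <- filter_zi(co$b, co$a)
  y <- .iir_filter_cpp(co$b, co$a, x, zi * x[1])
  y <- rev(y)
  y <- rev(.iir_filter_cpp(co$b, co$a, y, zi * y[1]))
  y[(npad + 1):(npad + n)]
}

#' Resample a uniformly sampled series to a lower rate
#'
#' Downsamples onto a uniform grid at `target_rate` covering the span of
#' `time`. An anti-alias low-pass at 80% of the target Nyquist is applied
#' first (skipped when the rate is unchanged), then values are read off
#' the new grid by linear interpolation, which also absorbs any phase
#' offset between the two device grids.
#'
#' @param series Numeric vector.
#' @param time Time stamps of `series`, seconds, strictly increasing.
#' @param target_rate Target sampling rate, Hz (default 100).
#' @param grid Optional explicit target time grid (e.g. the force sensor's
#'   time stamps); overrides the internally constructed grid.
#' @return List with `time` (the new grid) and `series`.
#' @export
resample_to <- function(series, time, target_rate = 100, grid = NULL) {
  stopifnot(length(series) == length(time))
  src_rate <- 1 / stats::median(diff(time))
  if (target_rate > src_rate * 1.001)
    stop("upsampling not supported: target rate exceeds source rate",
         call. = FALSE)
  x <- series
  if (target_rate < src_rate * 0.999) {
    aa <- filter_spec(4L, 0.8 * target_rate / 2)
    x <- lowpass_zero_lag(x, aa, src_rate)
  }
  if (is.null(grid)) {
    n_out <- floor((time[length(time)] - time[1]) * target_rate) + 1
    grid <- time[1] + (seq_len(n_out) - 1) / target_rate
  }
  y <- stats::approx(time, x, xout = grid, rule = 2)$y
  list(time = grid, series = y)
}
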