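#' Zero-phase band-pass filter
#'
#' Filters a regularly sampled signal in the frequency domain with a
#' raised-cosine transition band, which is exactly zero-phase and has a
#' closed-form frequency response ([bandpass_response()]).  The DC
#' component always lies in the stopband, so constant offsets are removed.
#'
#' @param x numeric signal
#' @param low,high passband corner frequencies in Hz; must satisfy
#'   `0 < low < high < Nyquist`
#' @param sampling_interval sample spacing in seconds
#' @param transition relative width of each raised-cosine transition edge
#'   (fraction of the corner frequency; default 0.5)
#' @return filtered signal of the same length
#' @examples
#' t <- seq(0, 400, by = 2)
#' x <- sin(2 * pi * 0.04 * t) + 3   # in-band tone plus offset
#' y <- bandpass_filter(x, 0.01, 0.08, 2)
#' @export
bandpass_filter <- function(x, low, high, sampling_interval, transition = 0.5) {
  if (!is.numeric(x) || length(x) < 8) stopf("signal must be numeric with >= 8 samples")
  if (any(!is.finite(x))) stopf("signal contains non-finite values")
  nyq <- 1 / (2 * sampling_interval)
  if (!(low > 0 && high > low && high < nyq)) {
    stopf("band (%g, %g) Hz must lie strictly inside (0, Nyquist = %g) Hz", low, high, nyq)
  }
  n <- length(x)
  f <- fft_bin_freqs(n, sampling_interval)
  H <- bandpass_response(f, low, high, transition)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# physical frequency of each FFT bin (folded; always >= 0)
fft_bin_freqs <- function(n, dt) {
  k <- 0:(n - 1)
  k <- pmin(k, n - k)
  k / (n * dt)
}

#' Frequency response of the band-pass filter
#'
#' Closed-form amplitude response applied by [bandpass_filter()]: unity on
#' `[low, high]`, raised-cosine roll-off over `[low*(1-transition), low]`
#' and `[high, high*(1+transition)]`, zero outside.  Useful as an analytic
#' oracle for the filter's behaviour.
#'
#' @inheritParams bandpass_filter
#' @param f frequencies (Hz) at which to evaluate the response
#' @return amplitude response in `[0, 1]` at each `f`
#' @export
bandpass_response <- function(f, low, high, transition = 0.5) {
  lo0 <- low * (1 - transition)
  hi1 <- high * (1 + transition)
  H <- numeric(length(f))
  pass <- f >= low & f <= high
  H[pass] <- 1
  rise <- f > lo0 & f < low
  H[rise] <- 0.5 * (1 - cos(pi * (f[rise] - lo0) / (low - lo0)))
  fall <- f > high & f < hi1
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - high) / (hi1 - high)))
  H
}

# analytic signal x + i H[x] via the FFT half-spectrum method
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a signal via the Hilbert transform
#'
#' The signal is demeaned (and by default linearly detrended) before the
#' analytic signal `x + iH[x]` is formed; the instantaneous phase is its
#' complex argument.
#'
#' @param x numeric signal, at least 8 samples, non-constant
#' @param detrend remove a linear trend first (default `TRUE`)
#' @param unwrap if `TRUE`, return the unwrapped (cumulative) phase;
#'   otherwise wrapped into `(-pi, pi]`
#' @return numeric phase series in radians, same length as `x`, with
#'   attribute `wrapped`
#' @examples
#' t <- 0:199
#' ph <- analytic_phase(cos(2 * pi * 0.05 * t))
#' @export
analytic_phase <- function(x, detrend = TRUE, unwrap = FALSE) {
  if (!is.numeric(x) || length(x) < 8) stopf("signal must be numeric with >= 8 samples")
  if (any(!is.finite(x))) stopf("signal contains non-finite values")
  if (isTRUE(detrend)) {
    tt <- seq_along(x)
    cf <- linear_fit(tt, x)
    x <- x - (cf[1] + cf[2] * tt)
  }
  x <- x - mean(x)
  if (sd(x) == 0) stopf("constant signal: instantaneous phase undefined")
  phi <- Arg(analytic_signal(x))
  if (unwrap) phi <- unwrap_phase(phi)
  structure(phi, wrapped = !unwrap)
}

# least-squares line fit (intercept, slope) without model.matrix overhead
linear_fit <- function(t, x) {
  tm <- mean(t); xm <- mean(x)
  b <- sum((t - tm) * (x - xm)) / sum((t - tm)^2)
  c(xm - b * tm, b)
}

# cumulative phase: undo 2*pi jumps
unwrap_phase <- function(phi) {
  d <- diff(phi)
  phi + 2 * pi * cumsum(c(0, round(-d / (2 * pi))))
}

#' Phase-locking value of a phase-difference series
#'
#' Mean resultant length of the wrapped phase difference,
#' `|mean(exp(i * dphi))|`.  Equals 1 iff the phase difference is constant
#' over the retained samples and tends to `sqrt(pi)/(2*sqrt(T))` for
#' independent uniform phase differences of length `T`.
#'
#' @param dphi phase differences in radians
#' @param trim fraction of samples dropped from each end before averaging
#'   (default 0, i.e. use every sample)
#' @return value in `[0, 1]`
#' @export
plv <- function(dphi, trim = 0) {
  idx <- trim_index(length(dphi), trim)
  min(1, Mod(mean(exp(1i * dphi[idx]))))
}

trim_index <- function(n, trim) {
  if (trim < 0 || trim >= 0.5) stopf("trim must be in [0, 0.5)")
  drop <- floor(n * trim)
  if (n - 2 * drop < 2) stopf("trim leaves fewer than 2 samples")
  (drop + 1):(n - drop)
}

#' Time-averaged phase-synchrony degree of two signals
#'
#' The 1:1 phase-synchrony degree: instantaneous phases are extracted with
#' [analytic_phase()] and the phase-locking value of their difference is
#' averaged over the interior of the record (the first and last `trim`
#' fraction of samples are excluded to suppress Hilbert end transients).
#' This is the functional connection strength between two regions; the
#' closer to its theoretical maximum 1, the stronger the synchrony.
#'
#' @param x,y numeric signals of equal length
#' @param trim end-trim fraction (default 0.05 per side)
#' @param detrend passed to [analytic_phase()]
#' @return phase-synchrony degree in `[0, 1]`
#' @examples
#' t <- 0:499
#' x <- cos(2 * pi * 0.05 * t)
#' ps_degree(x, cos(2 * pi * 0.05 * t - 1))  # constant lag: ~1
#' @export
ps_degree <- function(x, y, trim = 0.05, detrend = TRUE) {
  if (length(x) != length(y)) stopf("signals must have equal length")
  px <- analytic_phase(x, detrend = detrend)
  py <- analytic_phase(y, detrend = detrend)
  plv(as.numeric(px) - as.numeric(py), trim = trim)
}

#' Strict n:m phase-locking condition
#'
#' Tests the original bounded-phase-difference definition of phase
#' synchrony: whether `|n*phi_x(t) - m*phi_y(t) - c| <= eps` holds for all
#' interior samples for the best constant `c` (unwrapped phases; the best
#' sup-norm constant is the midrange).
#'
#' @inheritParams ps_degree
#' @param n,m positive integer locking ratios (typically 1)
#' @param eps radian bound, > 0
#' @return logical
#' @export
phase_locking_condition <- function(x, y, n = 1L, m = 1L, eps, trim = 0.05,
                                    detrend = TRUE) {
  if (length(x) != length(y)) stopf("signals must have equal length")
  if (n < 1 || m < 1 || n != round(n) || m != round(m)) stopf("n and m must be positive integers")
  if (!is.numeric(eps) || eps <= 0) stopf("eps must be a positive radian bound")
  px <- analytic_phase(x, detrend = detrend, unwrap = TRUE)
  py <- analytic_phase(y, detrend = detrend, unwrap = TRUE)
  d <- n * as.numeric(px) - m * as.numeric(py)
  d <- d[trim_index(length(d), trim)]
  (max(d) - min(d)) / 2 <= eps
}
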