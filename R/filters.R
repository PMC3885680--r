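# Butterworth IIR design (bilinear transform) and zero-phase application.
#
# The response contracts here are zero phase (forward-reverse application),
# >= 40 dB attenuation in the stop region and < 2-5 % passband ripple; a
# Butterworth realization meets them with no free ripple parameters.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0i) - c(0i, p * rk)
  p
}

# analog prototype -> digital (b, a) via bilinear transform at rate fs
bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Design a digital Butterworth filter
#'
#' Pure-R Butterworth design via the bilinear transform with frequency
#' pre-warping, supporting low-pass, high-pass and band-pass types.
#'
#' @param n filter order (for `"pass"`, the order of the low-pass prototype;
#'   the resulting band-pass has order `2 n`).
#' @param fc cutoff frequency in Hz (length 2 for `"pass"`).
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_filter <- function(n, fc, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(fc <= 0) || any(fc >= fs / 2))
    stop("cutoff frequencies must lie in (0, fs/2)")
  k <- seq_len(n)
  p0 <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-circle LP prototype
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "low") {
    w <- warp(fc)
    bilinear_zpk(complex(0), w * p0, w^n, fs)
  } else if (type == "high") {
    w <- warp(fc)
    bilinear_zpk(rep(0 + 0i, n), w / p0, 1, fs)
  } else {
    if (length(fc) != 2L || fc[1] >= fc[2])
      stop("band-pass requires fc = c(low, high) with low < high")
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    # lp2bp: s -> (s^2 + w0^2) / (bw * s)
    disc <- sqrt((p0 * bw / 2)^2 - w0^2 + 0i)
    pbp <- c(p0 * bw / 2 + disc, p0 * bw / 2 - disc)
    bilinear_zpk(rep(0 + 0i, n), pbp, bw^n, fs)
  }
}

# second-order IIR notch (constrained pole-zero placement); `bw` is the
# -3 dB bandwidth in Hz
notch_biquad <- function(f0, bw, fs) {
  w0 <- 2 * pi * f0 / fs
  q <- f0 / bw
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  list(b = b, a = a)
}

# steady-state filter state for a unit step (makes filtfilt transients
# vanish for step-like edges); solves the DF2T state equations
lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- nfilt - 1L
  if (n == 0L) return(numeric(0))
  # companion-form: zi = (I - A)^{-1} B with A, B of the DF2T recursion
  A <- matrix(0, n, n)
  A[, 1] <- -a[2:(n + 1)]
  if (n > 1) A[1:(n - 1), 2:n] <- diag(n - 1)
  B <- b[2:(n + 1)] - a[2:(n + 1)] * b[1]
  as.numeric(solve(diag(n) - A, B))
}

#' Zero-phase (forward-reverse) IIR filtering
#'
#' Applies the filter forward and then reversed, with odd (reflected) edge
#' padding and steady-state initial conditions so the net result has zero
#' phase and squared magnitude response.
#'
#' @param b,a filter coefficients.
#' @param x numeric vector.
#' @param padlen number of reflected samples prepended/appended; default
#'   `3 * (max(length(a), length(b)) - 1)`, capped at `length(x) - 1`.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x, padlen = NULL) {
  if (!all(is.finite(x))) stop("input contains non-finite values")
  ntaps <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3L * (ntaps - 1L)
  padlen <- min(padlen, length(x) - 1L)
  if (length(x) <= ntaps * 3L)
    stop("input shorter than three filter lengths")
  zi <- lfilter_zi(b, a)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[(padlen + 1):2],
      x,
      2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  } else x
  y <- cpp_iir_filter(b, a, ext, zi * ext[1])
  y <- rev(cpp_iir_filter(b, a, rev(y), zi * y[length(y)]))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + length(x))]
  y
}

# apply a zero-phase filter to every channel of a recording
filter_recording <- function(rec, b, a, padlen = NULL) {
  out <- t(apply(rec$samples, 1L, filtfilt_zero_phase, b = b, a = a,
                 padlen = padlen))
  recording(out, rec$fs, rec$labels, rec$reference)
}

#' High-pass filter a recording
#'
#' Zero-phase high-pass (default 0.3 Hz, order-4 Butterworth applied
#' forward-reverse) removing DC and slow drifts before spectral analysis.
#' The pad length defaults to roughly three time constants of the cutoff so
#' edge transients decay inside the padding.
#'
#' @param rec a [recording()].
#' @param cutoff high-pass cutoff in Hz.
#' @param order filter order.
#' @return filtered [recording()].
#' @export
highpass <- function(rec, cutoff = 0.3, order = 4L) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * cutoff) stop("fs must exceed twice the cutoff")
  f <- butter_filter(order, cutoff, rec$fs, "high")
  padlen <- ceiling(3 * rec$fs / cutoff)
  filter_recording(rec, f$b, f$a, padlen = padlen)
}

#' Notch-filter power-line interference
#'
#' Zero-phase notch at the line frequency with a narrow transition band
#' (default 0.3 Hz); with `harmonics = TRUE` the harmonics below Nyquist
#' (e.g. 120, 180 Hz at fs = 1000) are notched as well, as needed for the
#' higher-bandwidth subdural recordings.
#'
#' The squared magnitude response of a second-order constrained notch is
#' applied in the frequency domain. A recursive forward-reverse realization
#' of a notch this narrow (quality factor 200) is numerically fragile - the
#' reverse pass re-amplifies the forward pass's resonant transient - whereas
#' the frequency-domain application is exactly zero phase with the identical
#' magnitude contract.
#'
#' @param rec a [recording()].
#' @param line_freq line frequency in Hz.
#' @param transition transition bandwidth in Hz.
#' @param harmonics also notch integer harmonics below Nyquist.
#' @return filtered [recording()].
#' @export
notch <- function(rec, line_freq = 60, transition = 0.3, harmonics = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (line_freq >= rec$fs / 2) stop("line_freq must be below fs/2")
  freqs <- if (harmonics) {
    seq(line_freq, rec$fs / 2 - transition, by = line_freq)
  } else line_freq
  n <- ncol(rec$samples)
  fgrid <- (seq_len(n) - 1) / n * rec$fs
  gain <- rep(1, n)
  for (f0 in freqs) {
    f <- notch_biquad(f0, transition, rec$fs)
    z <- exp(-2i * pi * fgrid / rec$fs)
    H <- (f$b[1] + f$b[2] * z + f$b[3] * z^2) /
      (f$a[1] + f$a[2] * z + f$a[3] * z^2)
    gain <- gain * Mod(H)^2          # squared: zero-phase two-pass contract
  }
  out <- rec$samples
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- Re(fft(fft(out[ch, ]) * gain, inverse = TRUE)) / n
  recording(out, rec$fs, rec$labels, rec$reference)
}
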