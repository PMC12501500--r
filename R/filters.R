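#' Zero-phase Butterworth bandpass filter
#'
#' Fifth-order (by default) IIR Butterworth bandpass applied forward and
#' backward, so the net filter has zero phase (no group delay) and an
#' effective order of `2 * order`. The signal is extended by odd-symmetric
#' reflection before filtering to suppress start-up transients.
#'
#' @param x numeric vector, the signal.
#' @param fs sampling frequency in Hz.
#' @param low_hz,high_hz passband edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order filter order of the one-way prototype (default 5).
#' @return filtered signal, same length as `x`.
#' @export
butter_bandpass <- function(x, fs, low_hz, high_hz, order = 5) {
  if (!all(is.finite(x))) stop("non-finite values in input signal")
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  filtfilt_padded(flt, x)
}

#' Zero-phase notch (band-stop) filter for line noise
#'
#' Attenuates narrow bands around each frequency in `freqs_hz` (default the
#' 50 Hz mains fundamental and its 100 Hz harmonic) with a third-order
#' Butterworth band-stop of half-width `width_hz`, applied zero-phase.
#'
#' @param x numeric vector.
#' @param fs sampling frequency in Hz.
#' @param freqs_hz frequencies to notch out, all below Nyquist.
#' @param width_hz half-width of each stop band in Hz.
#' @param order one-way filter order per notch.
#' @return filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, freqs_hz = c(50, 100), width_hz = 1, order = 3) {
  if (!all(is.finite(x))) stop("non-finite values in input signal")
  nyq <- fs / 2
  if (any(freqs_hz + width_hz >= nyq)) stop("notch frequency at or above Nyquist")
  for (f0 in freqs_hz) {
    flt <- signal::butter(order, c(f0 - width_hz, f0 + width_hz) / nyq, type = "stop")
    x <- filtfilt_padded(flt, x)
  }
  x
}

# Forward-backward filtering with odd-symmetric edge reflection (the same
# convention scipy.signal.filtfilt uses); signal::filtfilt alone leaves
# visible edge transients on IIR filters.
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  npad <- min(n - 1L, max(3L * (length(flt$b) + length(flt$a)), 100L))
  head_ext <- 2 * x[1] - x[(npad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(flt, c(head_ext, x, tail_ext))
  y[(npad + 1):(npad + n)]
}

#' Resample a signal to a lower rate
#'
#' Polyphase anti-aliased resampling (via [signal::resample]) from `fs_in`
#' to `fs_out`; upsampling is rejected because the pipeline only ever
#' decimates (e.g. 1000 Hz acquisitions down to the 250 Hz analysis rate).
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling frequencies in Hz.
#' @return resampled signal of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_to <- function(x, fs_in, fs_out = 250) {
  if (fs_out > fs_in) stop("upsampling not supported (fs_out > fs_in)")
  if (fs_out == fs_in) return(x)
  ratio <- fs_in / fs_out
  y <- if (abs(ratio - round(ratio)) < 1e-9) {
    signal::decimate(x, round(ratio))   # zero-phase anti-aliased decimation
  } else {
    frac <- .ratio(fs_out, fs_in)
    signal::resample(x, frac[1], frac[2])
  }
  n_out <- round(length(x) * fs_out / fs_in)
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

.ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  k <- g(round(p * 1e6), round(q * 1e6))
  c(round(p * 1e6) / k, round(q * 1e6) / k)
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' (Hilbert) amplitude envelope. Computed by zeroing negative frequencies
#' and doubling positive ones in the DFT.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
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

#' Hilbert amplitude envelope of a band-passed signal
#'
#' Bandpass-filters `x` (zero-phase Butterworth) and returns the modulus of
#' the analytic signal. The series is mirror-extended by `pad_s` seconds on
#' each side before the transform so that envelope edge artefacts fall
#' outside the returned window.
#'
#' @param x numeric vector.
#' @param fs sampling frequency in Hz.
#' @param band two-element passband in Hz (default the beta band, 13-30 Hz).
#' @param pad_s mirror padding duration in seconds.
#' @param order bandpass order.
#' @return numeric envelope, same length as `x`.
#' @export
band_envelope <- function(x, fs, band = c(13, 30), pad_s = 0.5, order = 5) {
  n <- length(x)
  npad <- min(n - 1L, round(pad_s * fs))
  xp <- c(rev(x[seq_len(npad)]), x, rev(x[(n - npad + 1):n]))
  xf <- butter_bandpass(xp, fs, band[1], band[2], order = order)
  env <- Mod(analytic_signal(xf))
  env[(npad + 1):(npad + n)]
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem.
#' Tapers are unit-energy (`sum(taper^2) == 1`) and sign-fixed so that
#' symmetric tapers have positive mean.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return `n x k` matrix, one taper per column, in decreasing order of
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  stopifnot(n >= 2, k >= 1, k < n)
  w <- nw / n
  t <- 0:(n - 1)
  diag_el <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_el <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_el
  A[cbind(1:(n - 1), 2:n)] <- off_el
  A[cbind(2:n, 1:(n - 1))] <- off_el
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(v) < 0) v <- -v                       # symmetric tapers: positive mean
    if (abs(sum(v)) < 1e-8 && v[2] < v[1]) v <- -v # antisymmetric: positive slope
    tapers[, j] <- v
  }
  tapers
}
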