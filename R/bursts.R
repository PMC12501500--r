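#' Morlet wavelet time-frequency power
#'
#' Squared magnitude of the complex Morlet wavelet transform at each
#' requested frequency, computed by FFT convolution with unit-energy
#' wavelets of `n_cycles` cycles.
#'
#' @param x numeric matrix `trials x samples`.
#' @param fs sampling frequency, Hz.
#' @param freqs frequencies of interest in Hz (default 13-30 in 1 Hz
#'   steps), all inside (0, Nyquist).
#' @param n_cycles wavelet width in cycles.
#' @return array `trials x freqs x samples` of power.
#' @export
morlet_power <- function(x, fs, freqs = seq(13, 30), n_cycles = 7) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (any(freqs <= 0 | freqs >= fs / 2)) stop("frequencies outside (0, Nyquist)")
  n <- ncol(x)
  n_tr <- nrow(x)
  out <- array(0, c(n_tr, length(freqs), n))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma * fs)
    tw <- (-half:half) / fs
    w <- exp(2i * pi * f * tw) * exp(-tw^2 / (2 * sigma^2))
    w <- w / sqrt(sum(Mod(w)^2))
    nfft <- stats::nextn(n + length(w) - 1, 2)
    W <- stats::fft(c(w, complex(nfft - length(w))))
    for (tr in seq_len(n_tr)) {
      X <- stats::fft(c(x[tr, ], numeric(nfft - n)))
      conv <- stats::fft(X * W, inverse = TRUE) / nfft
      out[tr, fi, ] <- Mod(conv[(half + 1):(half + n)])^2
    }
  }
  out
}

#' Trial-mean beta power time course for one channel
#'
#' Mean over the beta frequency axis of the Morlet power, then over kept
#' trials, giving one per-participant beta power time course. Apply
#' z-scoring and evoked subtraction to the epochs beforehand to match the
#' trial-averaged power analysis.
#'
#' @param epochs an [epoch_set()].
#' @param channel channel name or index.
#' @param freqs,n_cycles wavelet settings.
#' @param baseline_correct subtract the curve's whole-trial mean (the
#'   display/statistics convention for the modulation curves).
#' @return numeric vector, one value per epoch sample.
#' @export
beta_power_timecourse <- function(epochs, channel, freqs = seq(13, 30),
                                  n_cycles = 7, baseline_correct = FALSE) {
  m <- channel_matrix(epochs, channel)
  pw <- morlet_power(m, epochs$fs, freqs, n_cycles)
  curve <- apply(pw, 3, mean)
  if (baseline_correct) curve <- curve - mean(curve)
  curve
}

#' Mean un-baselined beta power in fixed windows
#'
#' Beta power of z-scored but NOT evoked-subtracted data, averaged over
#' trials, the given channels, the beta frequency axis and each window.
#' The two default windows are the whole trial (-1 to 5 s) and the
#' pre-movement second (-1 to 0 s).
#'
#' @param epochs an [epoch_set()], z-scored, evoked response retained.
#' @param channels channel names to average over.
#' @param windows named list of two-element windows in trigger-relative
#'   seconds.
#' @param freqs,n_cycles wavelet settings.
#' @return named numeric vector, one scalar per window.
#' @export
unbaselined_beta_power <- function(epochs, channels,
                                   windows = list(whole = c(-1, 5),
                                                  pre = c(-1, 0)),
                                   freqs = seq(13, 30), n_cycles = 7) {
  for (w in windows)
    if (w[1] < epochs$time[1] - 1e-9 ||
        w[2] > epochs$time[length(epochs$time)] + 1 / epochs$fs + 1e-9)
      stop("window outside the epoch")
  curves <- vapply(channels, function(ch) {
    m <- channel_matrix(epochs, ch)
    apply(morlet_power(m, epochs$fs, freqs, n_cycles), 3, mean)
  }, numeric(length(epochs$time)))
  curve <- rowMeans(curves)
  vapply(windows, function(w) {
    idx <- epochs$time >= w[1] - 1e-9 & epochs$time < w[2] - 1e-9
    mean(curve[idx])
  }, numeric(1))
}

#' Detect beta bursts by Hilbert-envelope thresholding
#'
#' Per trial: bandpass 13-30 Hz, Hilbert amplitude envelope, division by
#' that trial's envelope mean, then bursts = maximal runs of samples
#' strictly above the threshold. The threshold is the `threshold_pct`
#' percentile of the normalized envelope, pooled across all trials
#' (`threshold_scope = "pooled"`, the default) or computed per trial.
#' Runs shorter than one cycle of the band's lowest frequency
#' (`min_dur = 1/13` s, i.e. 20 samples at 250 Hz) are discarded.
#'
#' @param x numeric matrix `trials x samples` (raw or z-scored; the
#'   per-trial normalization makes detection scale-invariant).
#' @param fs sampling frequency, Hz.
#' @param band beta band in Hz.
#' @param threshold_pct percentile threshold (default 75).
#' @param min_dur minimum burst duration in seconds (strict `<` exclusion).
#' @param threshold_scope `"pooled"` or `"per_trial"`.
#' @param t_start epoch time of the first sample, seconds.
#' @return a `burst_events` object: list with `events` (one data.frame
#'   per trial: onset, offset, amplitude), `threshold`, `fs`, `t_start`,
#'   `n_samples`.
#' @export
detect_bursts <- function(x, fs, band = c(13, 30), threshold_pct = 75,
                          min_dur = 1 / band[1],
                          threshold_scope = c("pooled", "per_trial"),
                          t_start = -1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  threshold_scope <- match.arg(threshold_scope)
  if (ncol(x) < fs / band[1]) stop("fewer samples than one beta cycle")
  n_tr <- nrow(x)
  env <- matrix(0, n_tr, ncol(x))
  for (tr in seq_len(n_tr)) {
    e <- band_envelope(x[tr, ], fs, band)
    me <- mean(e)
    if (me <= 0) stop("per-trial envelope mean must be positive")
    env[tr, ] <- e / me
  }
  thr_pooled <- stats::quantile(env, threshold_pct / 100, names = FALSE)
  events <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    thr <- if (threshold_scope == "pooled") thr_pooled
           else stats::quantile(env[tr, ], threshold_pct / 100, names = FALSE)
    events[[tr]] <- envelope_runs(env[tr, ], thr, fs, min_dur, t_start)
  }
  structure(list(events = events, threshold = thr_pooled, fs = fs,
                 t_start = t_start, n_samples = ncol(x), band = band,
                 min_dur = min_dur),
            class = "burst_events")
}

# maximal runs strictly above thr, duration rule applied
envelope_runs <- function(env, thr, fs, min_dur, t_start) {
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # strict exclusion: a run whose duration is < min_dur is dropped
  sel <- r$values & !(r$lengths / fs < min_dur)
  data.frame(
    onset = t_start + (starts[sel] - 1) / fs,
    offset = t_start + (ends[sel] - 1 + 1) / fs,
    amplitude = vapply(which(sel), function(i)
      max(env[starts[i]:ends[i]]), numeric(1))
  )
}

#' @export
print.burst_events <- function(x, ...) {
  n_ev <- sum(vapply(x$events, nrow, integer(1)))
  cat(sprintf("<burst_events> %d trials, %d events, pooled threshold %.3f\n",
              length(x$events), n_ev, x$threshold))
  invisible(x)
}

#' Burst metrics over a scoring window
#'
#' Fractional occupancy (burst time intersected with the window, divided
#' by the window length, averaged over trials), mean burst duration and
#' mean peak amplitude over events overlapping the window (durations are
#' NOT clipped to the window; only the occupancy numerator is), and the
#' event count. Duration and amplitude are NA when no event overlaps.
#'
#' @param bursts a `burst_events` object from [detect_bursts()].
#' @param window scoring window in trigger-relative seconds (default the
#'   1-3 s contraction phase).
#' @return list with `fractional_occupancy`, `mean_duration_s`,
#'   `mean_amplitude`, `n_bursts`.
#' @export
burst_metrics <- function(bursts, window = c(1, 3)) {
  wlen <- diff(window)
  fo_tr <- vapply(bursts$events, function(ev) {
    if (nrow(ev) == 0) return(0)
    sum(pmax(0, pmin(ev$offset, window[2]) - pmax(ev$onset, window[1]))) / wlen
  }, numeric(1))
  pooled <- do.call(rbind, bursts$events)
  sel <- pooled$offset > window[1] & pooled$onset < window[2]
  n_b <- sum(sel)
  list(fractional_occupancy = mean(fo_tr),
       mean_duration_s = if (n_b > 0) mean(pooled$offset[sel] - pooled$onset[sel]) else NA_real_,
       mean_amplitude = if (n_b > 0) mean(pooled$amplitude[sel]) else NA_real_,
       n_bursts = n_b)
}

#' Burst probability time course
#'
#' At each epoch sample, the fraction of trials that are inside a burst.
#'
#' @param bursts a `burst_events` object.
#' @param baseline_correct subtract the curve's whole-trial mean.
#' @return numeric vector of length `bursts$n_samples`.
#' @export
burst_probability_timecourse <- function(bursts, baseline_correct = FALSE) {
  n <- bursts$n_samples
  fs <- bursts$fs
  t0 <- bursts$t_start
  raster <- matrix(FALSE, length(bursts$events), n)
  for (tr in seq_along(bursts$events)) {
    ev <- bursts$events[[tr]]
    for (i in seq_len(nrow(ev))) {
      a <- round((ev$onset[i] - t0) * fs) + 1L
      b <- round((ev$offset[i] - t0) * fs)
      raster[tr, a:min(b, n)] <- TRUE
    }
  }
  p <- colMeans(raster)
  if (baseline_correct) p <- p - mean(p)
  p
}
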