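#' Cut a continuous recording into trigger-locked epochs
#'
#' Extracts a fixed window around each trigger sample. Triggers whose
#' window would run off either end of the recording are dropped with a
#' warning. The window is half-open, so `(-1, 5)` at 250 Hz yields exactly
#' 1500 samples with the trigger at t = 0.
#'
#' @param continuous numeric matrix `channels x samples`.
#' @param fs sampling frequency in Hz.
#' @param trigger_samples integer sample indices (1-based) of trial onsets.
#' @param window epoch window in seconds relative to each trigger.
#' @param channels channel table (see [epoch_set()]).
#' @param task task label.
#' @return an [epoch_set()].
#' @export
epoch_events <- function(continuous, fs, trigger_samples, window = c(-1, 5),
                         channels = NULL, task = "bilateral") {
  stopifnot(is.matrix(continuous))
  n_samp <- round((window[2] - window[1]) * fs)
  offsets <- round(window[1] * fs) + seq_len(n_samp) - 1L
  total <- ncol(continuous)
  ok <- trigger_samples + offsets[1] >= 1 & trigger_samples + offsets[n_samp] <= total
  if (any(!ok))
    warning(sum(!ok), " trigger(s) too close to a recording edge; dropped")
  trigs <- trigger_samples[ok]
  if (is.null(channels))
    channels <- data.frame(name = paste0("ch", seq_len(nrow(continuous))),
                           role = "parcel", side = NA_character_)
  data <- array(0, c(length(trigs), nrow(continuous), n_samp))
  for (k in seq_along(trigs))
    data[k, , ] <- continuous[, trigs[k] + offsets, drop = FALSE]
  epoch_set(data, fs, channels, task = task, t_start = window[1])
}

#' Flag outlier epochs by the generalized ESD test on log-variance
#'
#' For each channel role separately, computes per-trial log variance
#' (summed over channels of that role) and applies the generalized extreme
#' studentized deviate (GESD) outlier test at level `alpha`. A trial
#' flagged in any role is marked rejected; surviving trials are unchanged.
#'
#' @param epochs an [epoch_set()] with at least 5 trials.
#' @param alpha significance level of the GESD test.
#' @param max_frac maximum fraction of trials the test may remove.
#' @return the epoch set with updated `keep` flags.
#' @export
reject_bad_epochs <- function(epochs, alpha = 0.05, max_frac = 0.2) {
  n <- dim(epochs$data)[1]
  if (n < 5) stop("need at least 5 trials for outlier rejection")
  bad <- rep(FALSE, n)
  for (role in unique(epochs$channels$role)) {
    ch <- which(epochs$channels$role == role)
    v <- vapply(seq_len(n), function(k) {
      m <- epochs$data[k, ch, , drop = FALSE]
      log(mean(apply(matrix(m, length(ch)), 1, stats::var)))
    }, numeric(1))
    bad <- bad | gesd_outliers(v, alpha = alpha,
                               max_out = max(1L, floor(max_frac * n)))
  }
  keep <- epochs$keep & !bad
  if (!any(keep)) stop("all trials rejected; cannot proceed")
  epochs$keep <- keep
  epochs
}

# Generalized ESD (Rosner 1983) two-sided outlier test; returns a logical
# mask of detected outliers.
gesd_outliers <- function(x, alpha = 0.05, max_out = max(1L, floor(0.2 * length(x)))) {
  n <- length(x)
  idx <- seq_len(n)
  removed <- integer(0)
  n_sig <- 0L
  for (i in seq_len(max_out)) {
    xi <- x[idx]
    if (length(xi) < 3 || stats::sd(xi) == 0) break
    dev <- abs(xi - mean(xi)) / stats::sd(xi)
    j <- which.max(dev)
    Ri <- dev[j]
    ni <- n - i + 1L
    p <- 1 - alpha / (2 * ni)
    tcrit <- stats::qt(p, ni - 2)
    lam <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    removed <- c(removed, idx[j])
    idx <- idx[-j]
    if (Ri > lam) n_sig <- i
  }
  out <- rep(FALSE, n)
  if (n_sig > 0) out[removed[seq_len(n_sig)]] <- TRUE
  out
}

#' Z-score a signal
#'
#' Subtracts the mean and divides by the sample standard deviation.
#'
#' @param x numeric vector with positive standard deviation.
#' @return standardized vector (mean 0, sd 1).
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant signal")
  (x - mean(x)) / s
}

#' Z-score every trial of selected channels in place
#'
#' Standardizes each (trial, channel) time course independently, the
#' granularity used before time-frequency transformation.
#'
#' @param epochs an [epoch_set()].
#' @param channels channel names/indices to standardize (default all).
#' @return the modified epoch set.
#' @export
zscore_epochs <- function(epochs, channels = NULL) {
  ch <- if (is.null(channels)) seq_len(dim(epochs$data)[2])
        else vapply(channels, channel_index, integer(1), epochs = epochs)
  for (i in ch) for (k in seq_len(dim(epochs$data)[1]))
    epochs$data[k, i, ] <- zscore(epochs$data[k, i, ])
  epochs
}

#' Subtract the evoked (across-trial mean) response from each trial
#'
#' Implements X(t) = U(t) - M(t): at every time point the mean over kept
#' trials M(t) is removed from each single-trial series U(t), isolating
#' induced activity from the phase-locked evoked response. After the call
#' the across-trial mean of the channel is zero at every sample.
#'
#' @param epochs an [epoch_set()] with at least 2 kept trials.
#' @param channels channel names/indices to correct (default all).
#' @return the modified epoch set.
#' @export
subtract_evoked <- function(epochs, channels = NULL) {
  kept <- which(epochs$keep)
  if (length(kept) < 2) stop("evoked subtraction needs at least 2 kept trials")
  ch <- if (is.null(channels)) seq_len(dim(epochs$data)[2])
        else vapply(channels, channel_index, integer(1), epochs = epochs)
  for (i in ch) {
    m <- epochs$data[kept, i, , drop = FALSE]
    dim(m) <- c(length(kept), dim(epochs$data)[3])
    evoked <- colMeans(m)
    epochs$data[kept, i, ] <- sweep(m, 2, evoked)
  }
  epochs
}

#' Full-wave rectify an EMG signal
#'
#' Elementwise absolute value. Rectification demodulates the beta-band
#' drive carried in the EMG amplitude envelope, which is what makes
#' corticomuscular coherence recoverable from surface EMG.
#'
#' @param emg numeric vector/array.
#' @return `abs(emg)`.
#' @export
rectify <- function(emg) abs(emg)

#' Rectify all EMG channels of an epoch set
#'
#' @param epochs an [epoch_set()].
#' @return the epoch set with `role == "emg"` channels rectified.
#' @export
rectify_emg <- function(epochs) {
  ch <- which(epochs$channels$role == "emg")
  for (i in ch) epochs$data[, i, ] <- abs(epochs$data[, i, ])
  epochs
}
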