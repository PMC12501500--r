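#' Multitaper auto- and cross-spectra over segments and trials
#'
#' Slides a `window_len`-sample window (with fractional `overlap`) over
#' each trial of two paired channels, applies DPSS tapers, and averages
#' the taper/segment/trial periodograms into auto-spectra `Sxx`, `Syy`
#' and the complex cross-spectrum `Sxy`. Averaging happens before any
#' coherence is formed (coherence of averages, not average of coherences).
#' With `window_len = 200` at 250 Hz the frequency grid has the 1.25 Hz
#' spacing used throughout the CMC analysis.
#'
#' @param x,y numeric matrices `trials x samples` (same shape).
#' @param fs sampling frequency, Hz.
#' @param window_len segment length in samples.
#' @param overlap fractional segment overlap in 0 to <1.
#' @param nw DPSS time-bandwidth product.
#' @param n_tapers number of DPSS tapers.
#' @return list with `freqs` (one-sided grid, Hz), `Sxx`, `Syy` (real),
#'   `Sxy` (complex) and `n_segments` (total averages taken).
#' @export
segment_cross_spectra <- function(x, y, fs, window_len = 200, overlap = 0.5,
                                  nw = 2, n_tapers = 3) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (nrow(x) < 2) stop("need at least 2 trials")
  ns <- ncol(x)
  if (window_len > ns) stop("segment window longer than the analysis span")
  step <- max(1L, round(window_len * (1 - overlap)))
  starts <- seq(1L, ns - window_len + 1L, by = step)
  tapers <- dpss_tapers(window_len, nw = nw, k = n_tapers)
  nfreq <- window_len %/% 2 + 1
  Sxx <- Syy <- numeric(nfreq)
  Sxy <- complex(nfreq)
  n_avg <- 0L
  for (tr in seq_len(nrow(x))) {
    for (s0 in starts) {
      seg_idx <- s0:(s0 + window_len - 1L)
      xs <- x[tr, seg_idx]
      ys <- y[tr, seg_idx]
      X <- stats::mvfft(tapers * xs)[seq_len(nfreq), , drop = FALSE]
      Y <- stats::mvfft(tapers * ys)[seq_len(nfreq), , drop = FALSE]
      Sxx <- Sxx + rowSums(Mod(X)^2)
      Syy <- Syy + rowSums(Mod(Y)^2)
      Sxy <- Sxy + rowSums(X * Conj(Y))
      n_avg <- n_avg + n_tapers
    }
  }
  list(freqs = (seq_len(nfreq) - 1) * fs / window_len,
       Sxx = Sxx / n_avg, Syy = Syy / n_avg, Sxy = Sxy / n_avg,
       n_segments = n_avg)
}

#' Corticomuscular coherence spectrum for one channel pair
#'
#' Magnitude-squared coherence `|Sxy|^2 / (Sxx * Syy)` between a cortical
#' parcel channel and an EMG channel, estimated by the multitaper method
#' over the 2-4 s epoch window (the 1-3 s post-trigger contraction phase
#' once the 1 s pre-trigger baseline is counted), restricted to grid bins
#' inside `freq_range`. Both channels are expected to be evoked-subtracted
#' and the EMG rectified before the call (see [prepare_cmc_epochs()]).
#'
#' @param epochs an [epoch_set()].
#' @param cortex_channel,emg_channel channel names or indices.
#' @param window_s analysis window in epoch seconds.
#' @param freq_range frequency range in Hz kept from the grid.
#' @param window_len,overlap,nw,n_tapers multitaper settings (see
#'   [segment_cross_spectra()]).
#' @return a `coherence_spectrum` object: list with `freqs`, `coh` (in
#'   0-1), `pair`, `window_s`, `n_segments`.
#' @export
coherence_spectrum <- function(epochs, cortex_channel, emg_channel,
                               window_s = c(2, 4), freq_range = c(8, 40),
                               window_len = 200, overlap = 0.5,
                               nw = 2, n_tapers = 3) {
  # window_s is expressed on the epoch-relative clock starting at 0
  idx <- which(epochs$time - epochs$time[1] >= window_s[1] - 1e-9 &
                 epochs$time - epochs$time[1] < window_s[2] - 1e-9)
  xm <- channel_matrix(epochs, cortex_channel)[, idx, drop = FALSE]
  ym <- channel_matrix(epochs, emg_channel)[, idx, drop = FALSE]
  sp <- segment_cross_spectra(xm, ym, epochs$fs, window_len, overlap,
                              nw, n_tapers)
  denom <- sp$Sxx * sp$Syy
  coh <- numeric(length(denom))
  ok <- denom > 0
  if (!all(ok)) warning("zero-power frequency bin; coherence set to 0")
  coh[ok] <- Mod(sp$Sxy[ok])^2 / denom[ok]
  keep <- sp$freqs >= freq_range[1] - 1e-9 & sp$freqs <= freq_range[2] + 1e-9
  structure(list(freqs = sp$freqs[keep], coh = pmin(1, coh[keep]),
                 pair = c(cortex = as.character(cortex_channel),
                          emg = as.character(emg_channel)),
                 window_s = window_s, n_segments = sp$n_segments),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %s ~ %s, %g-%g Hz (%d bins), window %g-%g s\n",
              x$pair["cortex"], x$pair["emg"], min(x$freqs), max(x$freqs),
              length(x$freqs), x$window_s[1], x$window_s[2]))
  invisible(x)
}

#' Prepare an epoch set for coherence estimation
#'
#' Applies the CMC preprocessing chain: evoked (across-trial mean)
#' subtraction separately on the cortical and EMG channels, then full-wave
#' rectification of the EMG.
#'
#' @param epochs an [epoch_set()].
#' @return the prepared epoch set.
#' @export
prepare_cmc_epochs <- function(epochs) {
  ch <- epochs$channels$name[epochs$channels$role %in% c("parcel", "emg")]
  epochs <- subtract_evoked(epochs, ch)
  rectify_emg(epochs)
}

#' Contralateral and ipsilateral motor CMC spectra
#'
#' Pairs the left/right motor cortex channels with the right/left EMG
#' channels: contralateral = (left cortex, right EMG) and (right cortex,
#' left EMG); ipsilateral = same-side pairs. The hemisphere label names
#' the cortex side. For unilateral tasks, pairings with an absent EMG side
#' are simply not returned.
#'
#' @param epochs a prepared [epoch_set()] (see [prepare_cmc_epochs()]).
#' @param motor_channels named character vector `c(left=, right=)` of
#'   cortex channel names.
#' @param emg_channels named character vector `c(left=, right=)`; entries
#'   set to `NA` are treated as absent.
#' @param ... passed to [coherence_spectrum()].
#' @return named list of `coherence_spectrum`, names
#'   `"<hemisphere>_<contra|ipsi>"`.
#' @export
motor_cmc <- function(epochs,
                      motor_channels = c(left = "left_motor", right = "right_motor"),
                      emg_channels = c(left = "emg_left", right = "emg_right"),
                      ...) {
  out <- list()
  for (hemi in c("left", "right")) {
    contra_emg <- emg_channels[[if (hemi == "left") "right" else "left"]]
    ipsi_emg <- emg_channels[[hemi]]
    if (!is.na(contra_emg) && contra_emg %in% epochs$channels$name)
      out[[paste0(hemi, "_contra")]] <-
        coherence_spectrum(epochs, motor_channels[[hemi]], contra_emg, ...)
    if (!is.na(ipsi_emg) && ipsi_emg %in% epochs$channels$name)
      out[[paste0(hemi, "_ipsi")]] <-
        coherence_spectrum(epochs, motor_channels[[hemi]], ipsi_emg, ...)
  }
  out
}

#' Mean beta CMC per (parcel, EMG) pair: whole-brain topography
#'
#' For every cortical parcel channel and every EMG channel, the coherence
#' spectrum over the 2-4 s window is averaged across grid bins inside the
#' beta band, giving one scalar per pair.
#'
#' @param epochs a prepared [epoch_set()].
#' @param beta_band band in Hz averaged over (default 13-30).
#' @param ... passed to [coherence_spectrum()].
#' @return data.frame (parcel, emg, beta_cmc).
#' @export
beta_cmc_topography <- function(epochs, beta_band = c(13, 30), ...) {
  parcels <- epochs$channels$name[epochs$channels$role == "parcel"]
  emgs <- epochs$channels$name[epochs$channels$role == "emg"]
  res <- expand.grid(parcel = parcels, emg = emgs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$beta_cmc <- mapply(function(p, e) {
    cs <- coherence_spectrum(epochs, p, e, freq_range = beta_band, ...)
    mean(cs$coh)
  }, res$parcel, res$emg)
  res
}

#' Mean coherence of a spectrum inside a band
#'
#' @param cs a `coherence_spectrum`.
#' @param band two-element band in Hz.
#' @return scalar mean coherence.
#' @export
band_mean_coherence <- function(cs, band = c(13, 30)) {
  sel <- cs$freqs >= band[1] - 1e-9 & cs$freqs <= band[2] + 1e-9
  mean(cs$coh[sel])
}
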