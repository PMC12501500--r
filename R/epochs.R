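#' Epoched multichannel recording
#'
#' Container for one task's epoched data: a `trials x channels x samples`
#' array at a fixed sampling rate, the epoch time axis, a channel table
#' (name, role, side), the task label and per-trial keep flags. The default
#' epoch window is the half-open interval [-1, +5) s around the "grip"
#' trigger, i.e. exactly 1500 samples at 250 Hz.
#'
#' @param data numeric array `trials x channels x samples`; no NaN allowed.
#' @param fs sampling frequency in Hz.
#' @param channels data.frame with columns `name`, `role` (one of
#'   `"parcel"`, `"emg"`, `"force"`) and `side` (`"left"`, `"right"` or NA).
#' @param task task label, one of `"bilateral"`, `"right"`, `"left"`.
#' @param t_start epoch start time in seconds relative to the trigger.
#' @param keep logical per-trial flags; rejected trials are excluded from
#'   all downstream averages.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels, task = "bilateral",
                      t_start = -1, keep = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (anyNA(data)) stop("epoch data contains NA/NaN")
  stopifnot(is.data.frame(channels),
            all(c("name", "role") %in% names(channels)),
            nrow(channels) == dim(data)[2])
  if (is.null(channels$side)) channels$side <- NA_character_
  if (is.null(keep)) keep <- rep(TRUE, dim(data)[1])
  stopifnot(length(keep) == dim(data)[1])
  structure(list(
    data = data, fs = fs,
    time = t_start + (seq_len(dim(data)[3]) - 1) / fs,
    channels = channels, task = task, keep = keep
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> task=%s: %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
              x$task, d[1], sum(x$keep), d[2], d[3], x$fs))
  cat(sprintf("  time %.3f..%.3f s; channels: %s\n", x$time[1],
              x$time[length(x$time)],
              paste(utils::head(x$channels$name, 8), collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

# index of a named channel
channel_index <- function(epochs, channel) {
  if (is.numeric(channel)) return(as.integer(channel))
  i <- match(channel, epochs$channels$name)
  if (is.na(i)) stop("no channel named '", channel, "'")
  i
}

#' Extract one channel as a trials x samples matrix
#'
#' @param epochs an [epoch_set()].
#' @param channel channel name or index.
#' @param kept_only drop rejected trials (default TRUE).
#' @return numeric matrix, kept trials x samples.
#' @export
channel_matrix <- function(epochs, channel, kept_only = TRUE) {
  i <- channel_index(epochs, channel)
  m <- epochs$data[, i, , drop = FALSE]
  dim(m) <- dim(epochs$data)[c(1, 3)]
  if (kept_only) m <- m[epochs$keep, , drop = FALSE]
  m
}

# sample indices whose epoch time lies in [from, to)
window_samples <- function(epochs, from, to) {
  which(epochs$time >= from - 1e-9 & epochs$time < to - 1e-9)
}
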