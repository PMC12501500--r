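#' Detect the grip interval on a force trace
#'
#' Onset = first sample where force exceeds `onset_threshold_N` and stays
#' above it for at least `min_hold_s`; offset = first later sample where
#' force stays below the threshold for at least `min_hold_s` (or the end
#' of the trace). Returns NULL when no qualifying interval exists, e.g.
#' for a sub-threshold trace or a one-sample spike.
#'
#' @param force numeric force trace in Newtons.
#' @param fs sampling frequency, Hz.
#' @param onset_threshold_N detection threshold (default 2 N).
#' @param min_hold_s sustain requirement in seconds (default 0.04).
#' @param t_start epoch time of the first sample.
#' @return `c(onset_s, offset_s)` or NULL.
#' @export
detect_grip_interval <- function(force, fs, onset_threshold_N = 2,
                                 min_hold_s = 0.04, t_start = -1) {
  if (!all(is.finite(force))) stop("non-finite force values")
  min_run <- max(1L, round(min_hold_s * fs))
  r <- rle(force > onset_threshold_N)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  up <- which(r$values & r$lengths >= min_run)
  if (length(up) == 0) return(NULL)
  i <- up[1]
  onset <- starts[i]
  # offset: first sustained sub-threshold run after the onset run
  down <- which(!r$values & r$lengths >= min_run & starts > onset)
  offset <- if (length(down) > 0) starts[down[1]] else length(force) + 1L
  c(onset_s = t_start + (onset - 1) / fs,
    offset_s = t_start + (offset - 1) / fs)
}

#' Per-trial behavioural metrics from the force channels
#'
#' For each kept trial and each active force channel: reaction time
#' (trigger to grip onset), grip length (onset to offset), excess force
#' (mean force above the 12 N required minimum during the grip interval)
#' and correctness (force inside the 12-17 N target band for at least
#' half of the nominal 3 s hold). Trials with no detected grip are marked
#' incorrect with NA reaction time.
#'
#' @param epochs an [epoch_set()] containing `role == "force"` channels.
#' @param force_band required force band in Newtons.
#' @param onset_threshold_N,min_hold_s grip detector settings.
#' @param nominal_hold_s nominal hold duration for the correctness rule.
#' @return data.frame with one row per (kept trial, active force channel):
#'   trial, side, reaction_time_s, grip_length_s, excess_force_N, correct.
#' @export
behavioural_metrics <- function(epochs, force_band = c(12, 17),
                                onset_threshold_N = 2, min_hold_s = 0.04,
                                nominal_hold_s = 3) {
  fch <- which(epochs$channels$role == "force")
  if (length(fch) == 0) stop("no force channels present")
  fs <- epochs$fs
  rows <- list()
  for (i in fch) {
    side <- epochs$channels$side[i]
    m <- channel_matrix(epochs, i)
    if (max(m) < onset_threshold_N) next  # inactive hand in a unilateral task
    for (k in seq_len(nrow(m))) {
      f <- m[k, ]
      iv <- detect_grip_interval(f, fs, onset_threshold_N, min_hold_s,
                                 t_start = epochs$time[1])
      if (is.null(iv)) {
        rows[[length(rows) + 1]] <- data.frame(
          trial = k, side = side, reaction_time_s = NA_real_,
          grip_length_s = NA_real_, excess_force_N = NA_real_,
          correct = FALSE)
        next
      }
      grip_idx <- epochs$time >= iv[1] & epochs$time < iv[2]
      in_band <- f >= force_band[1] & f <= force_band[2]
      correct <- sum(in_band) / fs >= 0.5 * nominal_hold_s
      rows[[length(rows) + 1]] <- data.frame(
        trial = k, side = side,
        reaction_time_s = unname(iv[1]),
        grip_length_s = unname(iv[2] - iv[1]),
        excess_force_N = mean(f[grip_idx]) - force_band[1],
        correct = correct)
    }
  }
  do.call(rbind, rows)
}

#' Per-participant behavioural summary
#'
#' Median reaction time, mean grip length, mean excess force and the
#' proportion of correct trials, pooling the active sides. Trials without
#' a detected grip are excluded from the reaction-time median but count
#' as incorrect.
#'
#' @param rows output of [behavioural_metrics()].
#' @return one-row data.frame.
#' @export
behaviour_summary <- function(rows) {
  data.frame(
    median_rt_s = stats::median(rows$reaction_time_s, na.rm = TRUE),
    mean_grip_length_s = mean(rows$grip_length_s, na.rm = TRUE),
    mean_excess_force_N = mean(rows$excess_force_N, na.rm = TRUE),
    prop_correct = mean(rows$correct)
  )
}
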