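#' Gripper task specification
#'
#' One task block of the gripper paradigm: bilateral (120 trials by
#' default) or unilateral left/right (60 trials). Epochs run from -1 to
#' +5 s around the "grip" trigger; the grip is held for a nominal 3 s at a
#' target force inside 12-17 N, with a 2 s rest between trials.
#'
#' @param task_label one of `"bilateral"`, `"right"`, `"left"`.
#' @param n_trials number of trials (defaults: 120 bilateral, 60 unilateral).
#' @param force_target_N two-element target force band in Newtons.
#' @return a `task_spec` list.
#' @export
task_spec <- function(task_label = c("bilateral", "right", "left"),
                      n_trials = NULL, force_target_N = c(12, 17)) {
  task_label <- match.arg(task_label)
  if (is.null(n_trials)) n_trials <- if (task_label == "bilateral") 120L else 60L
  stopifnot(n_trials >= 1, diff(force_target_N) > 0)
  structure(list(task_label = task_label, n_trials = as.integer(n_trials),
                 epoch_window = c(-1, 5), grip_on_s = c(0, 3), rest_s = 2,
                 force_target_N = force_target_N),
            class = "task_spec")
}

#' Group-level generative parameters
#'
#' All knobs of the synthetic cohort for one group: the task-modulated
#' cortical burst rate profile, burst duration/amplitude distributions,
#' tonic beta with movement-related desynchronization and post-grip
#' rebound, corticomuscular coupling strength, 1/f background noise, and
#' behavioural timing. Defaults describe the healthy-control group;
#' [group_params_als()] applies the patient-direction deltas.
#'
#' Rate profile (bursts/s over epoch time t): `burst_rate_base` before the
#' trigger; multiplied by `1 - desync_depth` inside the desynchronization
#' window; `hold_rate` during the 1-3 s contraction plateau; multiplied by
#' `rebound_gain` in a 1 s rebound window starting `rebound_delay` s after
#' the 3.3 s nominal rebound onset.
#'
#' @param burst_rate_base baseline burst rate, bursts/s.
#' @param desync_depth fractional rate reduction during the 0.1-0.9 s
#'   post-trigger desynchronization window (0-1).
#' @param hold_rate burst rate during the 1-3 s hold, bursts/s.
#' @param rebound_gain rate multiplier in the post-release rebound window.
#' @param rebound_delay extra delay of the rebound window, seconds.
#' @param dur_meanlog,dur_sdlog lognormal burst-duration parameters
#'   (seconds; defaults give a ~0.25 s median).
#' @param amp_mean,amp_jitter burst amplitude mean (in units of the
#'   background beta envelope) and lognormal jitter sd.
#' @param burst_edge_s raised-cosine taper length at each burst edge,
#'   seconds (bursts are cosine-tapered plateaus, so their boundaries are
#'   well defined for any envelope-threshold detector).
#' @param burst_freq_range burst carrier frequency range within 13-30 Hz.
#' @param tonic_beta_amp amplitude of the tonic beta oscillation; its
#'   envelope follows the same desynchronization/rebound shape as the rate.
#' @param kappa corticomuscular coupling strength (dimensionless, >= 0).
#' @param conduction_delay_s cortex-to-muscle conduction delay, seconds.
#' @param noise_exponent 1/f background slope (power ~ f^-exponent).
#' @param noise_amp background noise standard deviation.
#' @param emg_floor EMG baseline-tone floor amplitude.
#' @param rt_meanlog,rt_sdlog lognormal reaction-time parameters (median
#'   0.4 s by default).
#' @param release_jitter_sd sd of the grip-release time around 3 s.
#' @param age_mean,age_sd,p_male,p_missing_mri covariate distributions.
#' @return a `group_params` list.
#' @export
group_params <- function(burst_rate_base = 1.0, desync_depth = 0.75,
                         hold_rate = 0.9, rebound_gain = 1.6,
                         rebound_delay = 0,
                         dur_meanlog = log(0.25), dur_sdlog = 0.4,
                         amp_mean = 3.0, amp_jitter = 0.15,
                         burst_edge_s = 0.02,
                         burst_freq_range = c(16, 28),
                         tonic_beta_amp = 0.4,
                         kappa = 1, conduction_delay_s = 0.02,
                         noise_exponent = 1, noise_amp = 1,
                         emg_floor = 0.05,
                         rt_meanlog = log(0.4), rt_sdlog = 0.25,
                         release_jitter_sd = 0.08,
                         age_mean = 62, age_sd = 14, p_male = 0.55,
                         p_missing_mri = 0.1) {
  stopifnot(kappa >= 0, desync_depth >= 0, desync_depth <= 1,
            burst_rate_base >= 0, hold_rate >= 0,
            burst_freq_range[1] >= 13, burst_freq_range[2] <= 30)
  as.list(environment())
}

#' Patient-direction variant of a parameter set
#'
#' Applies the signed effect directions reported for the ALS group:
#' weakened corticomuscular coupling, fewer bursts during the hold, higher
#' burst amplitude, shallower desynchronization and a delayed rebound.
#' Magnitudes are free multipliers.
#'
#' @param base a [group_params()] list (healthy-control defaults).
#' @param kappa_scale,hold_rate_scale,amp_scale multipliers.
#' @param desync_scale multiplier on the desynchronization depth.
#' @param rebound_delay_add added rebound delay in seconds.
#' @return a modified `group_params` list.
#' @export
group_params_als <- function(base = group_params(), kappa_scale = 0.5,
                             hold_rate_scale = 0.6, amp_scale = 1.3,
                             desync_scale = 0.5, rebound_delay_add = 0.4) {
  base$kappa <- base$kappa * kappa_scale
  base$hold_rate <- base$hold_rate * hold_rate_scale
  base$amp_mean <- base$amp_mean * amp_scale
  base$desync_depth <- base$desync_depth * desync_scale
  base$rebound_delay <- base$rebound_delay + rebound_delay_add
  base
}

#' Burst rate profile lambda(t) of a parameter set
#'
#' @param params a [group_params()] list.
#' @param task_active does this channel follow the task modulation (TRUE
#'   for motor parcels) or keep the stationary baseline rate (FALSE)?
#' @return a vectorized function of epoch time (seconds) returning
#'   bursts/s.
#' @export
burst_rate_profile <- function(params, task_active = TRUE) {
  p <- params
  function(t) {
    r <- rep(p$burst_rate_base, length(t))
    if (!task_active) return(r)
    desync <- t >= 0.1 & t < 0.9
    r[desync] <- p$burst_rate_base * (1 - p$desync_depth)
    hold <- t >= 1 & t < 3
    r[hold] <- p$hold_rate
    reb0 <- 3.3 + p$rebound_delay
    reb <- t >= reb0 & t < reb0 + 1
    r[reb] <- p$burst_rate_base * p$rebound_gain
    r
  }
}

#' Draw burst events from an inhomogeneous Poisson process
#'
#' Onsets are drawn by thinning against the maximum of `rate_fn` over the
#' epoch; each event gets a lognormal duration and a jittered amplitude.
#' Overlapping events are merged into one interval (amplitude = max) and
#' events are truncated at the epoch edges.
#'
#' @param rate_fn vectorized rate function of epoch time, bursts/s, >= 0.
#' @param epoch_window two-element window in seconds.
#' @param dur_meanlog,dur_sdlog lognormal duration parameters.
#' @param amp_mean,amp_jitter amplitude mean and lognormal jitter sd.
#' @param freq_range burst carrier frequency range in Hz.
#' @return data.frame (onset, offset, amplitude, freq), time-ordered and
#'   non-overlapping, with attribute `n_raw` = event count before merging.
#' @export
simulate_burst_events <- function(rate_fn, epoch_window = c(-1, 5),
                                  dur_meanlog = log(0.25), dur_sdlog = 0.4,
                                  amp_mean = 2.5, amp_jitter = 0.15,
                                  freq_range = c(16, 28)) {
  t0 <- epoch_window[1]; t1 <- epoch_window[2]
  if (t1 <= t0) stop("zero-length epoch window")
  grid <- seq(t0, t1, length.out = 601)
  rates <- rate_fn(grid)
  if (any(rates < 0)) stop("negative burst rate")
  rmax <- max(rates)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), freq = numeric(0))
  attr(empty, "n_raw") <- 0L
  if (rmax == 0) return(empty)
  n_cand <- stats::rpois(1, rmax * (t1 - t0))
  if (n_cand == 0) return(empty)
  cand <- sort(stats::runif(n_cand, t0, t1))
  keep <- stats::runif(n_cand) < rate_fn(cand) / rmax
  onset <- cand[keep]
  n <- length(onset)
  if (n == 0) return(empty)
  dur <- stats::rlnorm(n, dur_meanlog, dur_sdlog)
  amp <- amp_mean * stats::rlnorm(n, 0, amp_jitter)
  freq <- stats::runif(n, freq_range[1], freq_range[2])
  offset <- pmin(onset + dur, t1)
  onset <- pmax(onset, t0)
  ev <- data.frame(onset = onset, offset = offset, amplitude = amp, freq = freq)
  ev <- ev[ev$offset > ev$onset, , drop = FALSE]
  merged <- merge_burst_intervals(ev)
  attr(merged, "n_raw") <- n
  merged
}

# merge overlapping intervals; amplitude = max, freq = freq of the
# higher-amplitude member
merge_burst_intervals <- function(ev) {
  if (nrow(ev) <= 1) return(ev)
  ev <- ev[order(ev$onset), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    j <- nrow(out)
    if (ev$onset[i] <= out$offset[j]) {
      out$offset[j] <- max(out$offset[j], ev$offset[i])
      if (ev$amplitude[i] > out$amplitude[j]) {
        out$amplitude[j] <- ev$amplitude[i]
        out$freq[j] <- ev$freq[i]
      }
    } else out <- rbind(out, ev[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' 1/f-shaped Gaussian background noise
#'
#' White Gaussian noise spectrally shaped so its power spectrum falls as
#' `f^-exponent`, rescaled to standard deviation `sd_out`.
#'
#' @param n number of samples.
#' @param fs sampling frequency in Hz.
#' @param exponent spectral slope (1 = pink noise; 0 = white).
#' @param sd_out output standard deviation.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, fs, exponent = 1, sd_out = 1) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd_out / stats::sd(w))
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n        # folded frequency magnitude
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(X * scale, inverse = TRUE) / n)
  x * sd_out / stats::sd(x)
}

#' Synthesize one cortical parcel channel
#'
#' Sum of 1/f background noise, a tonic beta oscillation whose envelope
#' follows the desynchronization/rebound profile, and one cosine-tapered
#' plateau (Tukey-windowed) sinusoid per true burst event. Also returns
#' the noise-free beta-band component (`beta_drive`) used to drive the
#' coupled EMG channel.
#'
#' @param events burst events from [simulate_burst_events()].
#' @param t epoch time axis in seconds.
#' @param fs sampling frequency in Hz.
#' @param params a [group_params()] list.
#' @param task_active whether the tonic envelope follows the task profile.
#' @param tonic_freq tonic beta carrier frequency, Hz.
#' @return list with `signal` and `beta_drive`, both length `length(t)`.
#' @export
synth_cortical_channel <- function(events, t, fs, params,
                                   task_active = TRUE, tonic_freq = 21) {
  stopifnot(nrow(events) == 0 ||
              (min(events$onset) >= t[1] - 1e-9 &&
                 max(events$offset) <= t[length(t)] + 1/fs + 1e-9))
  n <- length(t)
  rate_fn <- burst_rate_profile(params, task_active)
  rel_profile <- rate_fn(t) / max(params$burst_rate_base, 1e-12)
  tonic <- params$tonic_beta_amp * rel_profile *
    sin(2 * pi * tonic_freq * t + stats::runif(1, 0, 2 * pi))
  bursts <- numeric(n)
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      idx <- which(t >= events$onset[i] & t < events$offset[i])
      if (length(idx) < 2) next
      env <- tukey_window(length(idx), round(params$burst_edge_s * fs))
      ph <- stats::runif(1, 0, 2 * pi)
      bursts[idx] <- bursts[idx] +
        events$amplitude[i] * env * sin(2 * pi * events$freq[i] * t[idx] + ph)
    }
  }
  drive <- tonic + bursts
  noise <- if (params$noise_amp > 0)
    one_over_f_noise(n, fs, params$noise_exponent, params$noise_amp)
  else numeric(n)
  list(signal = drive + noise, beta_drive = drive)
}

#' Synthesize a coupled EMG channel and its force trace
#'
#' EMG is broadband noise, gated by the grip envelope, amplitude-modulated
#' by `1 + kappa * (delayed, normalized cortical beta drive)` (clipped at
#' zero), plus a small baseline-tone floor — a Rayleigh-envelope carrier
#' whose rectification recovers the beta coupling. Force is a trapezoid
#' reaching `force_level` N during the hold with multiplicative jitter.
#'
#' @param beta_drive noise-free cortical beta component (from
#'   [synth_cortical_channel()]).
#' @param t epoch time axis, seconds.
#' @param fs sampling frequency, Hz.
#' @param kappa coupling strength (>= 0).
#' @param conduction_delay_s cortex-to-muscle lag in seconds.
#' @param grip_envelope values in 0-1; coupling and force exist only where
#'   it is positive.
#' @param force_level target hold force in Newtons.
#' @param emg_floor baseline EMG noise amplitude.
#' @return list with `emg` and `force` vectors.
#' @export
synth_emg_channel <- function(beta_drive, t, fs, kappa, conduction_delay_s,
                              grip_envelope, force_level = 14.5,
                              emg_floor = 0.05) {
  if (kappa < 0) stop("kappa must be >= 0")
  stopifnot(all(grip_envelope >= 0), all(grip_envelope <= 1))
  n <- length(t)
  lag <- round(conduction_delay_s * fs)
  d <- c(numeric(lag), beta_drive)[seq_len(n)]
  s <- stats::sd(d)
  if (s > 0) d <- d / s
  modulation <- pmax(0, 1 + kappa * d)
  carrier <- stats::rnorm(n)
  emg <- grip_envelope * carrier * modulation + emg_floor * stats::rnorm(n)
  slow <- stats::filter(stats::rnorm(n), rep(1 / 25, 25), circular = TRUE)
  force <- force_level * grip_envelope * (1 + 0.02 * as.numeric(slow))
  force[force < 0] <- 0
  list(emg = emg, force = force)
}

# cosine-tapered plateau window; falls back to a Hann when the event is
# shorter than two tapers
tukey_window <- function(n, n_edge) {
  if (n_edge < 1 || n <= 2 * n_edge) {
    return(0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n)))
  }
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = n_edge + 1))[-1]
  c(ramp, rep(1, n - 2 * n_edge), rev(ramp))
}

# trapezoidal grip envelope: 0 until onset, linear ramp (ramp_s), hold at
# 1, ramp down after release
grip_envelope_trapezoid <- function(t, onset_s, release_s, ramp_s = 0.1) {
  env <- numeric(length(t))
  up <- (t - onset_s) / ramp_s
  down <- (release_s + ramp_s - t) / ramp_s
  env <- pmin(1, pmax(0, pmin(up, down)))
  env
}

#' Simulate one participant's session for one task
#'
#' Generates an [epoch_set()] with left/right motor parcels (plus optional
#' extra parcels), left/right EMG and force channels, and the ground truth
#' (true burst intervals per motor parcel, reaction times, coupling used).
#' For unilateral tasks only the active hand grips; the other EMG stays at
#' its baseline floor and its force at zero.
#'
#' @param spec a [task_spec()].
#' @param params a [group_params()] list.
#' @param fs sampling frequency, Hz.
#' @param n_extra_parcels additional task-inactive cortical channels
#'   (stationary burst statistics, no coupling).
#' @param seed integer RNG seed; identical seeds give identical sessions.
#' @return list with `epochs` ([epoch_set()]) and `truth` (list with
#'   per-trial events per motor channel, behavioural truth and parameters
#'   used).
#' @export
simulate_session <- function(spec, params, fs = 250, n_extra_parcels = 0,
                             seed = 1) {
  set.seed(seed)
  n_trials <- spec$n_trials
  t <- spec$epoch_window[1] + (seq_len(round(diff(spec$epoch_window) * fs)) - 1) / fs
  n <- length(t)
  sides_active <- switch(spec$task_label,
                         bilateral = c("left", "right"),
                         right = "right", left = "left")
  parcel_names <- c("left_motor", "right_motor",
                    if (n_extra_parcels > 0) paste0("parcel_", seq_len(n_extra_parcels)))
  channels <- rbind(
    data.frame(name = c("left_motor", "right_motor"), role = "parcel",
               side = c("left", "right")),
    if (n_extra_parcels > 0)
      data.frame(name = paste0("parcel_", seq_len(n_extra_parcels)),
                 role = "parcel", side = NA_character_),
    data.frame(name = c("emg_left", "emg_right"), role = "emg",
               side = c("left", "right")),
    data.frame(name = c("force_left", "force_right"), role = "force",
               side = c("left", "right"))
  )
  data <- array(0, c(n_trials, nrow(channels), n))
  truth_events <- vector("list", n_trials)
  rt <- stats::rlnorm(n_trials, params$rt_meanlog, params$rt_sdlog)
  release <- 3 + stats::rnorm(n_trials, 0, params$release_jitter_sd)
  force_level <- stats::runif(n_trials, spec$force_target_N[1] + 0.5,
                              spec$force_target_N[2] - 0.5)
  rate_fn <- burst_rate_profile(params, task_active = TRUE)
  rate_fn_bg <- burst_rate_profile(params, task_active = FALSE)
  for (k in seq_len(n_trials)) {
    grip_env <- grip_envelope_trapezoid(t, rt[k], release[k])
    drives <- list()
    ev_trial <- list()
    for (pn in parcel_names) {
      active <- pn %in% c("left_motor", "right_motor")
      ev <- simulate_burst_events(if (active) rate_fn else rate_fn_bg,
                                  spec$epoch_window,
                                  params$dur_meanlog, params$dur_sdlog,
                                  params$amp_mean, params$amp_jitter,
                                  params$burst_freq_range)
      ch <- synth_cortical_channel(ev, t, fs, params, task_active = active)
      data[k, match(pn, channels$name), ] <- ch$signal
      drives[[pn]] <- ch$beta_drive
      if (active) ev_trial[[pn]] <- ev
    }
    for (side in c("left", "right")) {
      active <- side %in% sides_active
      contra <- if (side == "left") "right_motor" else "left_motor"
      ge <- if (active) grip_env else numeric(n)
      out <- synth_emg_channel(drives[[contra]], t, fs,
                               if (active) params$kappa else 0,
                               params$conduction_delay_s, ge,
                               force_level[k], params$emg_floor)
      data[k, match(paste0("emg_", side), channels$name), ] <- out$emg
      data[k, match(paste0("force_", side), channels$name), ] <- out$force
    }
    truth_events[[k]] <- ev_trial
  }
  epochs <- epoch_set(data, fs, channels, task = spec$task_label,
                      t_start = spec$epoch_window[1])
  truth <- list(events = truth_events, kappa = params$kappa,
                rt = rt, release = release, force_level = force_level,
                params = params, seed = seed, task = spec$task_label)
  list(epochs = epochs, truth = truth)
}

#' Ground-truth fractional occupancy over a scoring window
#'
#' Fraction of the window covered by true burst intervals, averaged over
#' trials, computed directly from the interval arithmetic of the truth.
#'
#' @param truth truth list from [simulate_session()].
#' @param channel motor channel name.
#' @param window scoring window in epoch seconds (default the 1-3 s
#'   contraction phase).
#' @return scalar in 0-1.
#' @export
truth_fo <- function(truth, channel = "left_motor", window = c(1, 3)) {
  fo <- vapply(truth$events, function(ev_tr) {
    ev <- ev_tr[[channel]]
    if (is.null(ev) || nrow(ev) == 0) return(0)
    covered <- sum(pmax(0, pmin(ev$offset, window[2]) - pmax(ev$onset, window[1])))
    covered / diff(window)
  }, numeric(1))
  mean(fo)
}

#' Ground-truth mean burst duration
#'
#' Mean duration of true burst intervals overlapping a scoring window,
#' pooled over trials (intervals are not clipped to the window).
#'
#' @inheritParams truth_fo
#' @return mean duration in seconds (NA if no events).
#' @export
truth_mean_duration <- function(truth, channel = "left_motor", window = c(1, 3)) {
  durs <- unlist(lapply(truth$events, function(ev_tr) {
    ev <- ev_tr[[channel]]
    if (is.null(ev) || nrow(ev) == 0) return(numeric(0))
    sel <- ev$offset > window[1] & ev$onset < window[2]
    ev$offset[sel] - ev$onset[sel]
  }))
  if (length(durs) == 0) return(NA_real_)
  mean(durs)
}

#' Simulate a two-group cohort
#'
#' Draws covariates and one session per task for each participant of two
#' groups (healthy-control-like and patient-like). Per-session seeds are
#' derived deterministically from `master_seed`, so identical master seeds
#' reproduce the cohort exactly.
#'
#' @param params_hc,params_als [group_params()] for the two groups.
#' @param n_per_group participants per group (>= 2).
#' @param tasks list of [task_spec()]s.
#' @param master_seed integer seed.
#' @param fs sampling frequency, Hz.
#' @param n_extra_parcels extra task-inactive parcels per session.
#' @return list with `participants` (covariate data.frame), `sessions`
#'   (list indexed `[[participant_id]][[task_label]]` of [epoch_set()]s)
#'   and `truth` (same indexing).
#' @export
simulate_cohort <- function(params_hc, params_als, n_per_group,
                            tasks = list(task_spec("bilateral")),
                            master_seed = 1, fs = 250, n_extra_parcels = 0) {
  stopifnot(n_per_group >= 2)
  set.seed(master_seed)
  n_total <- 2L * n_per_group
  ids <- sprintf("sub%03d", seq_len(n_total))
  if (anyDuplicated(ids)) stop("duplicate participant identifiers")
  groups <- rep(c("HC", "ALS"), each = n_per_group)
  plist <- list(HC = params_hc, ALS = params_als)
  participants <- data.frame(
    participant_id = ids, group = groups,
    age = pmax(30, pmin(88, round(stats::rnorm(n_total,
      mean = vapply(groups, function(g) plist[[g]]$age_mean, 1),
      sd = vapply(groups, function(g) plist[[g]]$age_sd, 1))))),
    sex = ifelse(stats::runif(n_total) <
      vapply(groups, function(g) plist[[g]]$p_male, 1), "M", "F"),
    missing_mri = stats::runif(n_total) <
      vapply(groups, function(g) plist[[g]]$p_missing_mri, 1)
  )
  # synthetic clinical covariates (scores only meaningful for patients)
  participants$alsfrs_r <- ifelse(groups == "ALS",
    pmax(10, pmin(48, round(stats::rnorm(n_total, 38, 6)))), NA)
  participants$ecas <- pmax(60, pmin(136, round(stats::rnorm(n_total,
    ifelse(groups == "ALS", 113, 118), ifelse(groups == "ALS", 9, 10)))))
  seeds <- matrix(sample.int(.Machine$integer.max - 1, n_total * length(tasks)),
                  n_total, length(tasks))
  sessions <- truths <- stats::setNames(vector("list", n_total), ids)
  for (i in seq_len(n_total)) {
    sessions[[i]] <- truths[[i]] <- list()
    for (j in seq_along(tasks)) {
      s <- simulate_session(tasks[[j]], plist[[groups[i]]], fs = fs,
                            n_extra_parcels = n_extra_parcels,
                            seed = seeds[i, j])
      sessions[[i]][[tasks[[j]]$task_label]] <- s$epochs
      truths[[i]][[tasks[[j]]$task_label]] <- s$truth
    }
  }
  list(participants = participants, sessions = sessions, truth = truths)
}
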