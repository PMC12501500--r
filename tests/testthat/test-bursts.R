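test_that("Morlet power is flat for a pure tone and peaks at its frequency", {
  x <- sin(2 * pi * 20 * EPOCH_T)
  pw <- morlet_power(matrix(x, 1), FS)
  core <- 200:1300
  tc <- apply(pw[1, , core], 2, mean)
  expect_lt(stats::sd(tc) / mean(tc), 0.05)          # CV away from edges
  prof <- rowMeans(pw[1, , core])
  expect_equal(seq(13, 30)[which.max(prof)], 20)
  expect_equal(morlet_power(matrix(0, 1, 1500), FS),
               array(0, c(1, 18, 1500)))
  expect_error(morlet_power(matrix(x, 1), FS, freqs = c(20, 200)), "Nyquist")
})

test_that("beta power scales with amplitude squared across a step", {
  env <- rep(1, length(EPOCH_T)); env[EPOCH_T >= 2] <- 2
  pw <- morlet_power(matrix(am_signal(env), 1), FS)
  tc <- apply(pw[1, , ], 2, mean)
  before <- mean(tc[EPOCH_T > 0.5 & EPOCH_T < 1.5])
  after <- mean(tc[EPOCH_T > 2.5 & EPOCH_T < 3.5])
  expect_equal(after / before, 4, tolerance = 0.1)
})

test_that("un-baselined beta power windows behave as constructed", {
  ch <- data.frame(name = "m", role = "parcel", side = NA)
  # stationary beta: the two windows agree
  data <- array(am_signal(rep(1, 1500)) + 0.1 * rnorm(1500), c(1, 1, 1500))
  ep <- epoch_set(data, FS, ch, t_start = -1)
  ub <- unbaselined_beta_power(ep, "m")
  expect_lt(abs(ub["whole"] / ub["pre"] - 1), 0.1)
  # beta only after t = 0
  data2 <- array(am_signal(as.numeric(EPOCH_T > 0)) + 1e-3 * rnorm(1500),
                 c(1, 1, 1500))
  ep2 <- epoch_set(data2, FS, ch, t_start = -1)
  ub2 <- unbaselined_beta_power(ep2, "m")
  expect_gt(ub2[["whole"]], 50 * ub2[["pre"]])
  expect_error(unbaselined_beta_power(ep, "m", windows = list(c(-2, 0))),
               "outside")
})

test_that("burst detection recovers a constructed excursion", {
  # rectangular envelope 1 -> 3 over [1.0, 1.5); with only 8% of samples
  # high, the pooled 75th percentile sits at baseline level, so the run
  # boundaries land on the band-limited envelope edge (~filter smear,
  # symmetric, well under half a beta cycle) around the true edges
  x <- am_signal(rect_envelope(1, 1.5, 3))
  bv <- detect_bursts(matrix(x, 1), FS, t_start = -1)
  ev <- bv$events[[1]]
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset - 1.0), 12 / FS)
  expect_lt(abs(ev$offset - 1.5), 12 / FS)
  mean_env <- (1 * 5.5 + 3 * 0.5) / 6
  expect_equal(ev$amplitude, 3 / mean_env, tolerance = 0.1)
})

test_that("burst edges are exact when the threshold lands mid-edge", {
  # excursion occupying 25% of samples puts the pooled percentile on the
  # steep part of the envelope edge: recovery to the sample
  for (carrier in c(17, 25)) {
    x <- am_signal(rect_envelope(1, 2.5, 3), freq = carrier)
    ev <- detect_bursts(matrix(x, 1), FS, t_start = -1)$events[[1]]
    main <- ev[which.max(ev$offset - ev$onset), ]
    expect_lt(abs(main$onset - 1.0), 2 / FS + 1e-9)
    expect_lt(abs(main$offset - 2.5), 2 / FS + 1e-9)
  }
})

test_that("the one-cycle duration rule excludes short excursions", {
  # 50 ms < 1/13 s minimum; a long companion excursion brings ~25% of
  # samples to the high level so the pooled threshold sits mid-edge and
  # run lengths match the excursions (a threshold at baseline level would
  # widen the short run by the filter smear instead)
  env <- rect_envelope(1, 2.44, 3)
  env[EPOCH_T >= 3.5 & EPOCH_T < 3.55] <- 3     # the 50 ms excursion
  ev <- detect_bursts(matrix(am_signal(env), 1), FS, t_start = -1)$events[[1]]
  expect_equal(nrow(ev), 1)
  expect_true(all(ev$onset < 3))                 # only the long event survives
  # a flat envelope yields no events
  expect_equal(nrow(detect_bursts(matrix(am_signal(rep(1, 1500)), 1),
                                  FS)$events[[1]]), 0)
  expect_error(detect_bursts(matrix(1, 1, 10), FS), "one beta cycle")
})

test_that("supra-threshold occupancy is 25% before the duration rule", {
  set.seed(61)
  for (i in 1:5) {
    x <- matrix(rnorm(4 * 1500), 4)
    bv <- detect_bursts(x, FS, min_dur = 0)
    fo <- burst_metrics(bv, window = c(-1, 5))$fractional_occupancy
    expect_equal(fo, 0.25, tolerance = 2 / 1500)
  }
})

test_that("the duration rule only removes events, never reshapes them", {
  set.seed(62)
  x <- matrix(rnorm(3 * 1500), 3)
  all_ev <- detect_bursts(x, FS, min_dur = 0)$events
  kept_ev <- detect_bursts(x, FS)$events
  for (tr in 1:3) {
    expect_true(all(kept_ev[[tr]]$offset - kept_ev[[tr]]$onset >= 1 / 13 - 1e-12))
    merged <- merge(kept_ev[[tr]], all_ev[[tr]])
    expect_equal(nrow(merged), nrow(kept_ev[[tr]]))   # survivors unchanged
  }
})

test_that("detection is invariant to per-trial scaling", {
  set.seed(63)
  x <- matrix(rnorm(2 * 1500), 2)
  ev1 <- detect_bursts(x, FS)$events
  x[1, ] <- x[1, ] * 123.4
  x[2, ] <- x[2, ] * 0.017
  ev2 <- detect_bursts(x, FS)$events
  for (tr in 1:2) expect_equal(ev1[[tr]], ev2[[tr]], tolerance = 1e-9)
})

test_that("noise-free synthetic bursts are recovered with high overlap", {
  set.seed(64)
  p <- group_params(noise_amp = 0.15, tonic_beta_amp = 0.1)
  sess <- simulate_session(task_spec("bilateral", n_trials = 20), p, seed = 64)
  bev <- detect_bursts(channel_matrix(sess$epochs, "left_motor"), FS,
                       t_start = -1)
  jac <- c()
  for (tr in 1:20) {
    tru <- sess$truth$events[[tr]]$left_motor
    det <- bev$events[[tr]]
    for (i in seq_len(nrow(tru))) {
      ov <- pmax(0, pmin(det$offset, tru$offset[i]) - pmax(det$onset, tru$onset[i]))
      j <- which.max(ov)
      if (length(j) && ov[j] > 0) {
        un <- max(det$offset[j], tru$offset[i]) - min(det$onset[j], tru$onset[i])
        jac <- c(jac, ov[j] / un)
      } else jac <- c(jac, 0)
    }
  }
  expect_gt(mean(jac > 0.75), 0.9)
  expect_gt(mean(jac), 0.8)
})

test_that("burst metrics arithmetic over the scoring window", {
  bv <- structure(list(events = list(data.frame(onset = 1.5, offset = 2.0,
                                                amplitude = 2)),
                       threshold = 1, fs = FS, t_start = -1,
                       n_samples = 1500, band = c(13, 30), min_dur = 1 / 13),
                  class = "burst_events")
  bm <- burst_metrics(bv, window = c(1, 3))
  expect_equal(bm$fractional_occupancy, 0.25)
  expect_equal(bm$mean_duration_s, 0.5)
  expect_equal(bm$n_bursts, 1)
  bv$events <- list(data.frame(onset = numeric(0), offset = numeric(0),
                               amplitude = numeric(0)))
  bm0 <- burst_metrics(bv, window = c(1, 3))
  expect_equal(bm0$fractional_occupancy, 0)
  expect_true(is.na(bm0$mean_duration_s))
})

test_that("burst probability time course counts bursting trials", {
  ev <- lapply(1:4, function(i) data.frame(onset = 1, offset = 2, amplitude = 1))
  bv <- structure(list(events = ev, threshold = 1, fs = FS, t_start = -1,
                       n_samples = 1500, band = c(13, 30), min_dur = 1 / 13),
                  class = "burst_events")
  p <- burst_probability_timecourse(bv)
  expect_equal(p[EPOCH_T >= 1 & EPOCH_T < 2], rep(1, 250))
  expect_equal(sum(p), 250)
  bv$events <- lapply(1:4, function(i) data.frame(onset = numeric(0),
                                                  offset = numeric(0),
                                                  amplitude = numeric(0)))
  expect_equal(burst_probability_timecourse(bv), numeric(1500))
})

test_that("group rate dips in the truth appear in probability curves", {
  lower <- vapply(1:5, function(s) {
    pA <- group_params()
    pB <- group_params_als()   # hold-rate reduction in 1-3 s
    sA <- simulate_session(task_spec("bilateral", n_trials = 30), pA, seed = 400 + s)
    sB <- simulate_session(task_spec("bilateral", n_trials = 30), pB, seed = 500 + s)
    pa <- burst_probability_timecourse(
      detect_bursts(channel_matrix(sA$epochs, "left_motor"), FS, t_start = -1))
    pb <- burst_probability_timecourse(
      detect_bursts(channel_matrix(sB$epochs, "left_motor"), FS, t_start = -1))
    sel <- EPOCH_T >= 1.1 & EPOCH_T < 2
    mean(pb[sel]) < mean(pa[sel])
  }, logical(1))
  expect_gte(mean(lower), 0.9)
})
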