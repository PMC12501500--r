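noise_epochs <- function(n_trials = 6, seed = 1, couple = 0) {
  set.seed(seed)
  n <- 1500
  data <- array(rnorm(n_trials * 2 * n), c(n_trials, 2, n))
  if (couple > 0) data[, 2, ] <- data[, 2, ] + couple * data[, 1, ]
  epoch_set(data, FS, data.frame(name = c("ctx", "emg_right"),
                                 role = c("parcel", "emg"),
                                 side = c("left", "right")), t_start = -1)
}

test_that("identical channels give coherence exactly 1 (Cauchy-Schwarz)", {
  set.seed(51)
  x <- matrix(rnorm(6 * 500), 6)
  sp <- segment_cross_spectra(x, x, FS)
  expect_equal(Mod(sp$Sxy)^2, sp$Sxx * sp$Syy, tolerance = 1e-10)
  ep <- noise_epochs()
  ep$data[, 2, ] <- ep$data[, 1, ]
  cs <- coherence_spectrum(ep, "ctx", "emg_right")
  expect_equal(cs$coh, rep(1, length(cs$coh)), tolerance = 1e-10)
})

test_that("the coherence grid is the 1.25 Hz multitaper grid within 8-40 Hz", {
  cs <- coherence_spectrum(noise_epochs(), "ctx", "emg_right")
  expect_equal(unique(round(diff(cs$freqs), 10)), 1.25)
  expect_gte(min(cs$freqs), 8)
  expect_lte(max(cs$freqs), 40)
  expect_true(all(cs$coh >= 0 & cs$coh <= 1))
})

test_that("independent-noise coherence sits at the 1/L bias floor", {
  set.seed(52)
  m <- replicate(60, {
    a <- matrix(rnorm(5 * 400), 5)
    b <- matrix(rnorm(5 * 400), 5)
    sp <- segment_cross_spectra(a, b, FS, overlap = 0)
    mean(Mod(sp$Sxy)^2 / (sp$Sxx * sp$Syy))
  })
  L <- 5 * 2 * 3   # trials x non-overlapping segments x tapers
  se <- stats::sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 1 / L), 2 * se + 0.002)
})

test_that("shared-sinusoid coherence matches the (s/(1+s))^2 closed form", {
  set.seed(53)
  n <- 12; ns <- 400
  tt <- outer(rep(1, n), (0:(ns - 1)) / FS)
  s0 <- sin(2 * pi * 20 * tt + stats::runif(n, 0, 2 * pi))
  a <- s0 + matrix(rnorm(n * ns), n)
  b <- s0 + matrix(rnorm(n * ns), n)
  sp <- segment_cross_spectra(a, b, FS, overlap = 0)
  k <- which.min(abs(sp$freqs - 20))
  # empirical per-bin SNR from signal-only / noise-only spectra
  s_pow <- segment_cross_spectra(s0, s0, FS, overlap = 0)$Sxx[k]
  n_pow <- segment_cross_spectra(matrix(rnorm(n * ns), n),
                                 matrix(rnorm(n * ns), n), FS,
                                 overlap = 0)$Sxx[k]
  snr <- s_pow / n_pow
  got <- Mod(sp$Sxy[k])^2 / (sp$Sxx[k] * sp$Syy[k])
  expect_lt(abs(got - (snr / (1 + snr))^2), 0.05)
})

test_that("coherence is invariant to trial order and channel scaling", {
  ep <- noise_epochs(couple = 0.7)
  cs <- coherence_spectrum(ep, "ctx", "emg_right")
  ep_perm <- ep
  ep_perm$data <- ep$data[c(4, 1, 6, 2, 5, 3), , ]
  expect_equal(coherence_spectrum(ep_perm, "ctx", "emg_right")$coh, cs$coh,
               tolerance = 1e-12)   # summation order differs in floating point
  ep_scaled <- ep
  ep_scaled$data[, 1, ] <- ep$data[, 1, ] * 37.5
  expect_equal(coherence_spectrum(ep_scaled, "ctx", "emg_right")$coh, cs$coh,
               tolerance = 1e-12)
})

test_that("motor CMC returns the contralateral/ipsilateral pairings", {
  sess <- simulate_session(task_spec("bilateral", n_trials = 8),
                           group_params(), seed = 54)
  mc <- motor_cmc(prepare_cmc_epochs(sess$epochs))
  expect_setequal(names(mc),
                  c("left_contra", "left_ipsi", "right_contra", "right_ipsi"))
  expect_identical(unname(mc$left_contra$pair), c("left_motor", "emg_right"))
  expect_identical(unname(mc$right_contra$pair), c("right_motor", "emg_left"))
  # absent EMG side: only defined pairings are returned
  mc2 <- motor_cmc(prepare_cmc_epochs(sess$epochs),
                   emg_channels = c(left = NA, right = "emg_right"))
  expect_setequal(names(mc2), c("left_contra", "right_ipsi"))
})

test_that("simulated coupling is contralateral: contra > ipsi in beta", {
  wins <- vapply(1:6, function(s) {
    sess <- simulate_session(task_spec("bilateral", n_trials = 20),
                             group_params(), seed = 200 + s)
    mc <- motor_cmc(prepare_cmc_epochs(sess$epochs))
    band_mean_coherence(mc$left_contra) > band_mean_coherence(mc$left_ipsi)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("beta CMC is monotone in the coupling strength", {
  kap <- c(0, 0.5, 2)
  means <- vapply(kap, function(k) {
    mean(vapply(1:5, function(s) {
      p <- group_params(); p$kappa <- k
      sess <- simulate_session(task_spec("bilateral", n_trials = 15), p,
                               seed = 300 + s)
      band_mean_coherence(motor_cmc(prepare_cmc_epochs(sess$epochs))$left_contra)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("topography localizes coupling to the driving parcel", {
  sess <- simulate_session(task_spec("right", n_trials = 20),
                           group_params(), n_extra_parcels = 3, seed = 55)
  topo <- beta_cmc_topography(prepare_cmc_epochs(sess$epochs))
  right_emg <- topo[topo$emg == "emg_right", ]
  expect_equal(right_emg$parcel[which.max(right_emg$beta_cmc)], "left_motor")
  # uncoupled parcels sit below twice the bias floor
  L <- sum(sess$epochs$keep) * 4 * 3
  bg <- right_emg$beta_cmc[!right_emg$parcel %in% c("left_motor", "right_motor")]
  expect_true(all(bg < 2 * (1 / L) * 3 + 0.01))
})

test_that("a parcel duplicating the EMG has topography value 1", {
  ep <- noise_epochs()
  ep$data[, 2, ] <- ep$data[, 1, ]
  topo <- beta_cmc_topography(ep)
  expect_equal(topo$beta_cmc, 1, tolerance = 1e-10)
})
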