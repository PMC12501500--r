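# constructed signals shared across tests

FS <- 250
EPOCH_T <- seq(-1, 5 - 1 / FS, by = 1 / FS)

# amplitude-modulated beta carrier: envelope `env` times a sinusoid
am_signal <- function(env, freq = 21, t = EPOCH_T) env * sin(2 * pi * freq * t)

# rectangular envelope excursion on a unit baseline
rect_envelope <- function(from, to, high, t = EPOCH_T) {
  env <- rep(1, length(t))
  env[t >= from & t < to] <- high
  env
}

# ideal trapezoid force trace (Newtons)
trapezoid_force <- function(level, onset, offset, t = EPOCH_T, ramp = 0.08) {
  level * pmin(1, pmax(0, pmin((t - onset) / ramp, (offset + ramp - t) / ramp)))
}
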