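# Fixtures built in code: small recordings and datasets shared across tests.

# deterministic multi-channel recording of pure tones (one freq per channel,
# recycled), amplitudes in microvolts
tone_recording <- function(freqs, amps = 50, dur = 10, fs = 200,
                           nch = 18L, id = "tone") {
  t <- seq(1 / fs, dur, by = 1 / fs)
  freqs <- rep_len(freqs, nch)
  amps <- rep_len(amps, nch)
  samples <- t(vapply(seq_len(nch), function(ch) {
    amps[ch] * sin(2 * pi * freqs[ch] * t)
  }, numeric(length(t))))
  recording(samples, fs, id = id, t0 = 0)
}

noise_recording <- function(dur = 10, fs = 200, nch = 18L, sd = 10,
                            seed = 1, id = "noise") {
  n <- round(dur * fs)
  samples <- pgesdetect:::with_seed(seed,
    matrix(rnorm(nch * n, sd = sd), nrow = nch))
  labels <- if (nch == 18L) pges_montage() else pges_montage()[seq_len(nch)]
  recording(samples, fs, channel_labels = labels, id = id, t0 = 0)
}

# small artifact-light simulated dataset reused by several tests
small_sim_dataset <- function(n = 4, dur = 60, seed = 99,
                              pges_range = c(10, 40)) {
  simulate_dataset(n, seed = seed,
                   params = simulation_params(duration = dur,
                                              pges_duration = NA),
                   pges_range = pges_range)
}

# raw periodogram band power (independent oracle used by synthetic tests)
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi & f <= fs / 2]) * 2
}
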