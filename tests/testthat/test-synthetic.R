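test_that("simulation is deterministic given the seed", {
  p <- simulation_params(duration = 20, pges_duration = 8, seed = 123)
  a <- simulate_recording(p)
  b <- simulate_recording(p)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$annotation, b$annotation)
})

test_that("suppression interval is quieter than the resumed background", {
  p <- simulation_params(duration = 80, pges_duration = 40, seed = 21)
  sim <- simulate_recording(p)
  s <- sim$recording$samples
  i_supp <- 1:(40 * 200)
  i_post <- (40 * 200 + 1):(80 * 200)
  for (ch in 1:18) {
    expect_lt(mean(abs(s[ch, i_supp])), mean(abs(s[ch, i_post])))
  }
  expect_equal(sim$annotation$pges_end, 40)
})

test_that("pges_duration beyond the window is rejected", {
  expect_error(simulation_params(duration = 60, pges_duration = 100),
               "exceeds")
})

test_that("a 10 uV peak-to-peak epoch threshold recovers the PGES boundary", {
  for (seed in c(3, 14, 159)) {
    dur <- 30 + seed %% 17
    p <- simulation_params(duration = 90, pges_duration = dur, seed = seed)
    sim <- simulate_recording(p)
    ep <- epoch_signal(sim$recording)
    p2p <- apply(ep$epochs, c(1, 2), function(v) diff(range(v)))
    suppressed <- apply(p2p, 2L, max) < 10  # all channels attenuated
    boundary <- which(!suppressed)[1L] - 1L  # epoch start in seconds
    expect_lte(abs(boundary - dur), 1)
  }
})

test_that("breathing artifacts concentrate 0.2-0.5 Hz power where injected", {
  arch <- artifact_archetype("breath", channels = 1:8, kind = "breathing",
                             onset = 10, offset = 20, intensity = 100)
  p <- simulation_params(duration = 60, pges_duration = 5, seed = 77,
                         archetypes = list(arch))
  sim <- simulate_recording(p)
  fs <- 200
  for (ch in c(1, 4, 8)) {
    active <- sim$recording$samples[ch, (10 * fs + 1):(20 * fs)]
    quiet <- sim$recording$samples[ch, (30 * fs + 1):(40 * fs)]
    expect_gt(oracle_band_power(active, fs, 0.2, 0.5),
              5 * oracle_band_power(quiet, fs, 0.2, 0.5))
  }
  # untouched channels stay quiet
  ch18_active <- sim$recording$samples[18, (10 * fs + 1):(20 * fs)]
  expect_lt(oracle_band_power(ch18_active, fs, 0.2, 0.5),
            oracle_band_power(sim$recording$samples[1, (10 * fs + 1):(20 * fs)],
                              fs, 0.2, 0.5) / 5)
})

test_that("dataset generation stratifies archetypes deterministically", {
  archs <- list(
    artifact_archetype("a", 1:8, "breathing", 10, 20, 100),
    artifact_archetype("b", 9:16, "movement", 10, 20, 100))
  ds <- simulate_dataset(10, archs, mix = c(0.5, 0.5), seed = 4,
                         params = simulation_params(duration = 30,
                                                    pges_duration = NA),
                         pges_range = c(5, 8))
  expect_length(ds, 10L)
  tags <- vapply(ds, `[[`, "", "archetype")
  expect_equal(unname(table(tags)[c("a", "b")]), c(5L, 5L),
               ignore_attr = TRUE)

  one <- simulate_dataset(4, archs[1], mix = 1, seed = 4,
                          params = simulation_params(duration = 30,
                                                     pges_duration = NA),
                          pges_range = c(5, 8))
  expect_true(all(vapply(one, `[[`, "", "archetype") == "a"))
  expect_error(simulate_dataset(0), "positive")

  # whole-dataset determinism
  ds2 <- simulate_dataset(10, archs, mix = c(0.5, 0.5), seed = 4,
                          params = simulation_params(duration = 30,
                                                     pges_duration = NA),
                          pges_range = c(5, 8))
  expect_identical(lapply(ds, function(d) d$recording$samples),
                   lapply(ds2, function(d) d$recording$samples))
})

test_that("disjoint-channel archetypes separate in artifact-band power", {
  archs <- list(
    artifact_archetype("temporal", 1:8, "breathing", 5, 25, 300),
    artifact_archetype("parasagittal", 9:16, "movement", 5, 25, 300))
  ds <- simulate_dataset(12, archs, seed = 31,
                         params = simulation_params(duration = 40),
                         pges_range = c(5, 10))
  fs <- 200
  # oracle: mean 0.2-2 Hz power on mask A minus mask B in the active window
  contrast <- vapply(ds, function(d) {
    win <- (5 * fs + 1):(25 * fs)
    pa <- mean(apply(d$recording$samples[1:8, win], 1L, oracle_band_power,
                     fs = fs, lo = 0.2, hi = 2))
    pb <- mean(apply(d$recording$samples[9:16, win], 1L, oracle_band_power,
                     fs = fs, lo = 0.2, hi = 2))
    pa - pb
  }, numeric(1L))
  tags <- vapply(ds, `[[`, "", "archetype")
  expect_gt(min(contrast[tags == "temporal"]), 0)
  expect_lt(max(contrast[tags == "parasagittal"]), 0)
})
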