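fs <- 200

test_that("a pure sinusoid is a fixed point of sifting", {
  t <- seq(1 / fs, 5, by = 1 / fs)
  x <- sin(2 * pi * 3 * t)
  y <- sift_one(x)
  expect_lt(sqrt(mean((y - x)^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("sifting separates a fast tone from a slow one", {
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t)
  imf1 <- sift_one(x)
  expect_gt(cor(imf1, sin(2 * pi * 20 * t)), 0.95)
})

test_that("monotone signals admit no IMF", {
  expect_error(sift_one(seq(0, 1, length.out = 100)), "no IMF extractable")
})

test_that("EMD reconstructs its input and orders modes by frequency", {
  # constant input: no modes, residual = input
  d0 <- emd(rep(2.5, 300))
  expect_equal(d0$n_modes, 0L)
  expect_equal(d0$residual, rep(2.5, 300))

  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t)
  d <- emd(x)
  expect_gte(d$n_modes, 2L)
  recon <- rowSums(d$imfs) + d$residual
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
  peak_freq <- function(v) {
    p <- Mod(fft(v))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    f[which.max(p[2:(length(v) %/% 2)]) + 1L]
  }
  expect_equal(peak_freq(d$imfs[, 1L]), 20, tolerance = 0.15)
  expect_equal(peak_freq(d$imfs[, 2L]), 2, tolerance = 0.25)
})

test_that("every decomposition reconstructs and yields valid IMFs", {
  t <- seq_len(400) / fs
  pgesdetect:::with_seed(29, {
    for (i in 1:20) {
      k <- sample(1:3, 1L)
      x <- rowSums(vapply(seq_len(k), function(j) {
        runif(1, 0.5, 3) * sin(2 * pi * runif(1, 1, 30) * t + runif(1, 0, 2 * pi))
      }, numeric(length(t)))) + rnorm(length(t), sd = 0.2)
      d <- emd(x)
      recon <- if (d$n_modes > 0) rowSums(d$imfs) + d$residual else d$residual
      expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
      for (j in seq_len(d$n_modes)) {
        ne <- pgesdetect:::count_extrema(d$imfs[, j])
        nz <- pgesdetect:::count_zero_crossings(d$imfs[, j])
        expect_lte(abs(ne - nz), 1L)
      }
      # residual admits no further IMF (or the mode cap was hit)
      ex <- pgesdetect:::.extrema_cpp(d$residual)
      expect_true(length(ex$maxima) < 2L || length(ex$minima) < 2L ||
                    d$n_modes == 10L)
    }
  })
})

test_that("the IMF criteria accept sinusoids and reject offset signals", {
  t <- seq(1 / fs, 2, by = 1 / fs)
  expect_true(is_imf(sin(2 * pi * 5 * t)))
  expect_false(is_imf(rep(1, 400)))
  # offset sine: no zero crossings but many extrema -> count rule fails
  offset <- 0.5 + 0.2 * sin(2 * pi * 5 * t)
  expect_equal(pgesdetect:::count_zero_crossings(offset), 0L)
  expect_gt(pgesdetect:::count_extrema(offset), 5L)
  expect_false(is_imf(offset))
})

test_that("Hilbert analysis recovers tone amplitude and frequency", {
  t <- seq(1 / fs, 10, by = 1 / fs)
  interior <- (2 * fs):(8 * fs)
  for (f in c(1, 2, 4, 10)) {
    A <- 2.5
    ha <- hilbert_analytic(A * sin(2 * pi * f * t), fs)
    expect_lt(max(abs(ha$amplitude[interior] - A)) / A, 0.02)
    expect_lt(max(abs(ha$frequency[interior] - f)) / f, 0.02)
  }
  expect_equal(hilbert_analytic(numeric(100) + 0, fs)$amplitude, numeric(100))
  # linearity: scaling the input scales amplitude, not frequency
  x <- sin(2 * pi * 4 * t)
  h1 <- hilbert_analytic(x, fs)
  h3 <- hilbert_analytic(3 * x, fs)
  expect_equal(h3$amplitude, 3 * h1$amplitude, tolerance = 1e-10)
  expect_equal(h3$frequency, h1$frequency, tolerance = 1e-10)
})

test_that("the epoch feature is zero on silence and scales with amplitude", {
  expect_equal(hht_epoch_feature(matrix(0, 1L, 200L), fs), 0)
  t <- seq(1 / fs, 1, by = 1 / fs)
  lo <- matrix(5 * sin(2 * pi * 2 * t), nrow = 1L)
  hi <- 10 * lo
  f_lo <- hht_epoch_feature(lo, fs)
  f_2x <- hht_epoch_feature(2 * lo, fs)
  f_10x <- hht_epoch_feature(hi, fs)
  expect_equal(f_2x / f_lo, 2, tolerance = 0.05)
  expect_gte(f_10x / f_lo, 8)
  expect_lte(f_10x / f_lo, 12)
})

test_that("the artifact map localizes low-frequency content and gates high", {
  t <- seq(1 / fs, 60, by = 1 / fs)
  s <- matrix(0, 18L, length(t))
  s[1L, ] <- 50 * sin(2 * pi * 2 * t)
  m <- artifact_feature_map(recording(s, fs), T_seconds = 60)
  expect_gt(mean(m[1L, ]), 10 * max(mean(m[-1L, ]), 1e-6))

  s20 <- matrix(rep(50 * sin(2 * pi * 20 * t), each = 18L), nrow = 18L)
  m20 <- artifact_feature_map(recording(s20, fs), T_seconds = 60,
                              normalize = FALSE)
  expect_lt(max(m20), 1e-6)

  m0 <- artifact_feature_map(recording(matrix(0, 18L, length(t)), fs),
                             T_seconds = 60)
  expect_true(all(m0 == 0))
})

test_that("the artifact map is insensitive to added 20-30 Hz content", {
  # a low-frequency artifact pattern on 6 channels over background noise
  t <- seq(1 / fs, 30, by = 1 / fs)
  samples <- pgesdetect:::with_seed(44, {
    s <- matrix(rnorm(18L * length(t), sd = 3), nrow = 18L)
    for (ch in 1:6) s[ch, ] <- s[ch, ] + 40 * sin(2 * pi * 1.5 * t + ch)
    s
  })
  rec <- recording(samples, fs, id = "slow", t0 = 0)
  base <- artifact_feature_map(bandpass(rec, 0.5, 30), T_seconds = 30)
  fast <- rec
  fast$samples <- fast$samples + matrix(rep(20 * sin(2 * pi * 25 * t),
                                            each = 18L), nrow = 18L)
  plus <- artifact_feature_map(bandpass(fast, 0.5, 30), T_seconds = 30)
  # the gated total moves < 10% and the spatiotemporal pattern is preserved
  expect_lt(abs(sum(plus) - sum(base)) / sum(base), 0.1)
  expect_gt(cor(as.numeric(base), as.numeric(plus)), 0.9)
})

test_that("short recordings yield a zero-padded, flagged map", {
  rec <- noise_recording(dur = 10, sd = 10, seed = 12)
  m <- artifact_feature_map(bandpass(rec, 0.5, 30), T_seconds = 30)
  expect_true(attr(m, "padded"))
  expect_true(all(m[, 11:30] == 0))
})
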