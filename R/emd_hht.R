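#' Extract one candidate intrinsic mode function by sifting
#'
#' One round of the sifting procedure: the upper and lower envelopes are
#' cubic splines through the local maxima and minima (mirror-extended by two
#' extrema at each boundary), their mean `m(t) = (s-(t) + s+(t)) / 2` is
#' subtracted, and the subtraction is repeated on the result until a Cauchy
#' criterion `sum(m^2) / sum(y^2) < sd_tol` holds or `max_iter` passes have
#' run.
#'
#' @param x Numeric signal with at least two maxima and two minima.
#' @param sd_tol Cauchy stopping tolerance (default 0.2).
#' @param max_iter Sifting iteration cap (default 50).
#' @return Numeric vector: the candidate IMF (same length as `x`).
#' @export
sift_one <- function(x, sd_tol = 0.2, max_iter = 50L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  .sift_cpp(as.numeric(x), sd_tol, as.integer(max_iter))
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) and a residual
#' by repeated sifting: `x(t) = sum_i IMF_i(t) + r_N(t)`. Each extracted IMF
#' is subtracted from the running residual and sifting continues until the
#' residual is monotone (fewer than two extrema) or `max_modes` modes have
#' been extracted. Modes come out ordered from highest to lowest dominant
#' frequency; the reconstruction identity holds exactly by construction.
#'
#' @param x Numeric signal.
#' @param max_modes Mode cap (default 10); prevents over-sifting noise.
#' @param sd_tol,max_iter Sifting controls, see [sift_one()].
#' @return An `imf_decomposition`: list with `imfs` (length x n_modes
#'   matrix), `residual`, and `n_modes`.
#' @export
emd <- function(x, max_modes = 10L, sd_tol = 0.2, max_iter = 50L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  res <- .emd_cpp(as.numeric(x), as.integer(max_modes), sd_tol,
                  as.integer(max_iter))
  structure(list(imfs = res$imfs, residual = as.numeric(res$residual),
                 n_modes = ncol(res$imfs)),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition: %d modes, %d samples>\n",
              x$n_modes, length(x$residual)))
  invisible(x)
}

# total count of local extrema and of zero crossings
count_extrema <- function(x) {
  ex <- .extrema_cpp(as.numeric(x))
  length(ex$maxima) + length(ex$minima)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Test whether a signal satisfies the IMF criteria
#'
#' A signal is an intrinsic mode function when (1) its number of local
#' extrema and of zero crossings differ by at most one, and (2) the mean of
#' its upper and lower extremal envelopes is near zero everywhere (RMS of
#' the envelope mean below `env_tol` times the signal RMS). When envelopes
#' cannot be constructed (fewer than two maxima or minima) the signal mean
#' stands in for the envelope mean, so a nonzero constant is not an IMF.
#'
#' @param x Numeric signal.
#' @param env_tol Envelope-mean tolerance relative to signal RMS
#'   (default 0.05).
#' @return Logical scalar.
#' @export
is_imf <- function(x, env_tol = 0.05) {
  stopifnot(is.numeric(x))
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(FALSE)
  if (abs(count_extrema(x) - count_zero_crossings(x)) > 1L) return(FALSE)
  em <- .envelope_mean_cpp(as.numeric(x))
  m_rms <- if (isTRUE(em$ok)) sqrt(mean(em$mean^2)) else abs(mean(x))
  m_rms <= env_tol * rms
}

#' Instantaneous amplitude and frequency via the Hilbert transform
#'
#' Forms the analytic signal by one-sided spectral doubling (FFT), then
#' returns its modulus as instantaneous amplitude and the derivative of the
#' unwrapped phase (central differences, times `fs / 2 pi`) as instantaneous
#' frequency, clipped to `[0, fs/2]`.
#'
#' @param x Numeric signal (ideally a single IMF).
#' @param fs Sampling frequency in Hz.
#' @return List with `amplitude` and `frequency` (Hz), both length of `x`.
#' @export
hilbert_analytic <- function(x, fs) {
  n <- length(x)
  stopifnot(n > 2L, fs > 0)
  z <- fft(fft(x) * .hilbert_h(n), inverse = TRUE) / n
  amp <- Mod(z)
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))  # unwrap increments
  inst <- c(dph[1L], (dph[-1L] + dph[-(n - 1L)]) / 2, dph[n - 1L]) * fs / (2 * pi)
  list(amplitude = amp, frequency = pmin(pmax(inst, 0), fs / 2))
}

# one-sided spectral doubling weights for the analytic signal
.hilbert_h <- function(n) {
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  h
}

# Hilbert-amplitude sum over all modes of one signal (rows batched via mvfft)
.hht_amp_sum <- function(x, fs, max_modes, sd_tol = 0.2, max_iter = 50L) {
  dec <- .emd_cpp(as.numeric(x), as.integer(max_modes), sd_tol,
                  as.integer(max_iter))
  if (ncol(dec$imfs) == 0L) return(0)
  n <- nrow(dec$imfs)
  Z <- stats::mvfft(dec$imfs) * .hilbert_h(n)
  sum(Mod(stats::mvfft(Z, inverse = TRUE))) / n
}

#' Per-epoch Hilbert spectral amplitude feature
#'
#' The EMD-based epoch feature: for each channel of a 1-second epoch (taken
#' from the 0.5-30 Hz filtered signal), decompose by [emd()] and sum the
#' Hilbert amplitude of every mode over all samples. Degenerate epochs that
#' yield no modes score 0.
#'
#' @param epoch Numeric matrix, channels x samples, one epoch.
#' @param fs Sampling frequency in Hz.
#' @param max_modes Mode cap passed to [emd()].
#' @return Numeric vector, one amplitude sum per channel.
#' @export
hht_epoch_feature <- function(epoch, fs, max_modes = 10L) {
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = 1L)
  vapply(seq_len(nrow(epoch)), function(ch) {
    .hht_amp_sum(epoch[ch, ], fs, max_modes)
  }, numeric(1L))
}

#' Whole-recording low-frequency artifact feature map
#'
#' Summarizes a recording's artifact burden as an 18 x T matrix: for each
#' channel the full 0.5-30 Hz filtered signal is decomposed by [emd()], the
#' Hilbert amplitude of every mode is accumulated into 1-second time bins,
#' but only at samples whose instantaneous frequency falls in the
#' low-frequency band (0.5-5 Hz) where intermittent slow waves and the
#' major rhythmic artifacts live. The map is normalized by its own 95th
#' percentile (robust per-recording scale) so clustering compares
#' spatiotemporal patterns rather than absolute gain.
#'
#' @param rec A 0.5-30 Hz filtered postictal `pges_recording`.
#' @param T_seconds Time span of the map in seconds (default 300); shorter
#'   recordings are zero-padded and flagged (`attr(map, "padded")`).
#' @param band Frequency gate in Hz (default `c(0.5, 5)`).
#' @param max_modes Mode cap passed to [emd()].
#' @param normalize Divide by the 95th percentile (default `TRUE`).
#' @return An `artifact_feature_map`: channels x T_seconds matrix with
#'   channel labels as rownames.
#' @export
artifact_feature_map <- function(rec, T_seconds = 300, band = c(0.5, 5),
                                 max_modes = 10L, normalize = TRUE) {
  check_recording(rec, require_montage = FALSE)
  fs <- rec$fs
  n <- ncol(rec$samples)
  n_bins <- as.integer(T_seconds)
  spb <- as.integer(round(fs))  # samples per 1-s bin
  covered <- min(n_bins, as.integer(ceiling(n / spb)))
  use_bins <- seq_len(covered)
  vals <- matrix(0, nrow = nrow(rec$samples), ncol = n_bins)
  for (ch in seq_len(nrow(rec$samples))) {
    dec <- emd(rec$samples[ch, ], max_modes = max_modes)
    if (dec$n_modes == 0L) next
    acc <- numeric(covered)
    for (j in seq_len(dec$n_modes)) {
      ha <- hilbert_analytic(dec$imfs[, j], fs)
      amp <- ha$amplitude *
        (ha$frequency >= band[1L] & ha$frequency <= band[2L])
      length(amp) <- covered * spb  # pads a partial last bin with NA
      acc <- acc + colSums(matrix(amp, nrow = spb), na.rm = TRUE)
    }
    vals[ch, use_bins] <- acc
  }
  padded <- n < n_bins * fs
  if (normalize) {
    scale <- quantile(vals[, use_bins], 0.95, names = FALSE)
    if (scale > 0) vals <- vals / scale
  }
  rownames(vals) <- rec$channel_labels
  structure(vals, class = c("artifact_feature_map", "matrix", "array"),
            padded = padded)
}
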