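# Per-epoch feature bank: time-domain statistics and Hjorth parameters,
# low-frequency band powers, db4 wavelet energies, inter-channel
# correlations, plus the EMD/Hilbert epoch feature, assembled into one
# feature matrix per recording.

# db4 (8-tap Daubechies) orthonormal scaling filter
.db4_h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)

# one periodized DWT analysis step: x (even length) -> list(approx, detail)
.dwt_step <- function(x) {
  n <- length(x)
  h <- .db4_h
  g <- rev(h) * c(1, -1, 1, -1, 1, -1, 1, -1)
  half <- n / 2L
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(approx = a, detail = d)
}

#' Time-domain features of one epoch
#'
#' Statistical moments (mean, skewness, excess kurtosis) and Hjorth
#' parameters: activity = variance, mobility = sqrt(var(dx)/var(x)),
#' complexity = mobility(dx)/mobility(x), all with population (1/n)
#' variances. A zero-variance epoch returns 0 for skewness, kurtosis,
#' mobility and complexity.
#'
#' @param x Numeric vector, one channel of one epoch.
#' @return Named numeric vector: `mean`, `kurtosis`, `skewness`,
#'   `activity`, `mobility`, `complexity`.
#' @export
time_features <- function(x) {
  mu <- mean(x)
  c2 <- x - mu
  m2 <- mean(c2^2)
  if (m2 <= 0) {
    return(c(mean = mu, kurtosis = 0, skewness = 0, activity = 0,
             mobility = 0, complexity = 0))
  }
  skew <- mean(c2^3) / m2^1.5
  kurt <- mean(c2^4) / m2^2 - 3
  varp <- function(v) mean((v - mean(v))^2)
  dx <- diff(x)
  vdx <- varp(dx)
  mob <- sqrt(vdx / m2)
  comp <- if (vdx > 0) sqrt(varp(diff(dx)) / vdx) / mob else 0
  c(mean = mu, kurtosis = kurt, skewness = skew, activity = m2,
    mobility = mob, complexity = comp)
}

#' Low-frequency band powers of one epoch
#'
#' Periodogram power integrated over the slow-oscillation (0.5-1 Hz), delta
#' (1-4 Hz) and 4-5 Hz bands. Inputs are expected from the 0.5-5 Hz
#' filtered signal, so bands above 5 Hz are not computed. Band edges are
#' inclusive (a 1-second epoch has 1 Hz frequency resolution).
#'
#' @param x Numeric vector, one channel of one epoch.
#' @param fs Sampling frequency in Hz.
#' @param bands Matrix-like list of band edges; default the three bands.
#' @return Named numeric vector of band powers.
#' @export
band_powers <- function(x, fs,
                        bands = list(slow = c(0.5, 1), delta = c(1, 4),
                                     band4_5 = c(4, 5))) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  freq <- (seq_len(n) - 1L) * fs / n
  keep <- seq_len(floor(n / 2) + 1L)  # one-sided
  p <- p[keep] * c(1, rep(2, length(keep) - 2L), 1)
  freq <- freq[keep]
  vapply(bands, function(b) sum(p[freq >= b[1L] & freq <= b[2L]]),
         numeric(1L))
}

#' Wavelet energy features of one epoch
#'
#' Periodized orthonormal db4 discrete wavelet decomposition. The epoch is
#' zero-padded to the next power of two so the transform stays orthonormal
#' at every level; the energy (sum of squared coefficients) of each detail
#' level and of the final approximation is returned. Total coefficient
#' energy equals signal energy.
#'
#' @param x Numeric vector, one channel of one epoch.
#' @param levels Decomposition depth (default 4).
#' @return Named numeric vector `wav_d1` ... `wav_d<levels>`, `wav_a<levels>`.
#' @export
wavelet_features <- function(x, levels = 4L) {
  n2 <- 2^ceiling(log2(max(length(x), 2^levels)))
  xp <- c(x, numeric(n2 - length(x)))
  energies <- numeric(levels + 1L)
  names(energies) <- c(paste0("wav_d", seq_len(levels)),
                       paste0("wav_a", levels))
  a <- xp
  for (l in seq_len(levels)) {
    st <- .dwt_step(a)
    energies[l] <- sum(st$detail^2)
    a <- st$approx
  }
  energies[levels + 1L] <- sum(a^2)
  energies
}

#' Pairwise inter-channel correlations of one epoch
#'
#' Pearson correlation for every unordered channel pair in canonical order
#' (pair (i, j), i < j, by montage position). Pairs involving a
#' zero-variance channel score 0.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param labels Channel labels (default rownames).
#' @return Named numeric vector of `choose(n_channels, 2)` correlations.
#' @export
channel_correlations <- function(epoch, labels = rownames(epoch)) {
  nch <- nrow(epoch)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch))
  sds <- apply(epoch, 1L, sd)
  cc <- suppressWarnings(cor(t(epoch)))
  cc[!is.finite(cc)] <- 0
  cc[sds == 0, ] <- 0
  cc[, sds == 0] <- 0
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  out <- cc[pairs]
  names(out) <- paste0("cor_", gsub("-", ".", labels[pairs[, 1L]]), "_",
                       gsub("-", ".", labels[pairs[, 2L]]))
  out
}

#' Build the per-epoch feature matrix of one recording
#'
#' Filters the postictal window into the two analysis bands (0.5-30 Hz for
#' the EMD/Hilbert feature, 0.5-5 Hz for everything else), segments both
#' into 1-second epochs, and computes per channel: 6 time-domain features,
#' 3 band powers, 5 wavelet energies and the Hilbert-spectrum amplitude sum,
#' plus 153 inter-channel correlations per epoch. Epochs are labelled
#' `suppression` when their start time precedes the annotated PGES end,
#' `non_suppression` otherwise (all epochs when `has_pges` is `FALSE`).
#'
#' @param rec Postictal `pges_recording` (unfiltered, `t0 = 0`).
#' @param ann One-row annotation data frame for the recording.
#' @param emd_band,base_band Filter bands in Hz.
#' @param max_modes Mode cap for the EMD feature.
#' @return Data frame (class `epoch_feature_matrix`): columns
#'   `recording_id`, `epoch_index` (0-based), `epoch_start` (s), `label`,
#'   then the named feature columns in stable order. No missing values.
#' @export
build_feature_matrix <- function(rec, ann, emd_band = c(0.5, 30),
                                 base_band = c(0.5, 5), max_modes = 10L) {
  check_recording(rec)
  stopifnot(nrow(ann) == 1L)
  ep30 <- epoch_signal(bandpass(rec, emd_band[1L], emd_band[2L]))
  ep5 <- epoch_signal(bandpass(rec, base_band[1L], base_band[2L]))
  n_ep <- dim(ep5$epochs)[2L]
  nch <- dim(ep5$epochs)[1L]
  labels <- gsub("-", ".", rec$channel_labels)
  fs <- rec$fs

  per_channel <- vector("list", nch)
  for (ch in seq_len(nch)) {
    E5 <- ep5$epochs[ch, , , drop = TRUE]
    if (n_ep == 1L) E5 <- matrix(E5, nrow = 1L)
    tf <- t(apply(E5, 1L, time_features))
    bp <- t(apply(E5, 1L, band_powers, fs = fs))
    wv <- t(apply(E5, 1L, wavelet_features))
    hht <- vapply(seq_len(n_ep), function(e) {
      .hht_amp_sum(ep30$epochs[ch, e, ], fs, max_modes)
    }, numeric(1L))
    block <- cbind(tf, bp, wv, hht = hht)
    colnames(block) <- paste0(labels[ch], "_", colnames(block))
    per_channel[[ch]] <- block
  }
  cors <- t(vapply(seq_len(n_ep), function(e) {
    channel_correlations(ep5$epochs[, e, , drop = TRUE],
                         labels = rec$channel_labels)
  }, numeric(nch * (nch - 1L) / 2L)))

  feats <- do.call(cbind, c(per_channel, list(cors)))
  feats[!is.finite(feats)] <- 0
  p_end <- if (isTRUE(ann$has_pges)) ann$pges_end else 0
  lab <- ifelse(ep5$epoch_start < p_end, "suppression", "non_suppression")
  out <- data.frame(recording_id = rec$id,
                    epoch_index = seq_len(n_ep) - 1L,
                    epoch_start = ep5$epoch_start,
                    label = lab,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats))
  class(out) <- c("epoch_feature_matrix", "data.frame")
  out
}

# columns of an epoch_feature_matrix that are model features
feature_columns <- function(fm) {
  setdiff(names(fm), c("recording_id", "epoch_index", "epoch_start", "label"))
}

#' Write a feature matrix to CSV
#' @param fm An `epoch_feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.csv(fm, path, row.names = FALSE)
  invisible(path)
}
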