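#' Extract the postictal analysis window
#'
#' Cuts the window starting at the annotated seizure end out of a source
#' recording and re-origins time so that the window's first sample is at
#' `t0 = 0` (seconds after seizure end). Windows are capped at `duration`
#' seconds; when the file ends earlier the window is truncated with a
#' warning.
#'
#' @param rec Source `pges_recording` (file time).
#' @param ann One-row annotation data frame for this recording (see
#'   [annotation()]); `seizure_end` is interpreted on the file's time axis.
#' @param duration Maximum window length in seconds (default 300, i.e. the
#'   5-minute postictal window).
#' @return A `pges_recording` with `t0 = 0` and duration `<= duration`.
#' @export
extract_postictal <- function(rec, ann, duration = 300) {
  check_recording(rec, require_montage = FALSE)
  stopifnot(nrow(ann) == 1L, duration > 0)
  total <- recording_duration(rec)
  s_end <- ann$seizure_end
  if (s_end >= total) {
    stop("seizure_end (", s_end, " s) is at or beyond the end of recording '",
         rec$id, "' (", total, " s)")
  }
  avail <- total - s_end
  if (avail < duration) {
    warning("recording '", rec$id, "' ends ", round(avail, 3),
            " s after seizure end; truncating the ", duration, "-s window")
    duration <- avail
  }
  i0 <- floor(s_end * rec$fs) + 1L
  i1 <- min(ncol(rec$samples), i0 + floor(duration * rec$fs) - 1L)
  recording(rec$samples[, i0:i1, drop = FALSE], rec$fs,
            channel_labels = rec$channel_labels, id = rec$id, t0 = 0)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the passband is traversed twice (zero phase, no
#' epoch-timing shift). Each channel is reflectively padded by one filter
#' settling length before filtering to suppress edge transients.
#'
#' @param rec A `pges_recording`.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return Filtered `pges_recording` of identical shape.
#' @export
bandpass <- function(rec, low, high, order = 4L) {
  check_recording(rec, require_montage = FALSE)
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("invalid band [", low, ", ", high, "] Hz for fs = ", fs, " Hz")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- ncol(rec$samples)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / low)))
  filt <- rec$samples
  for (ch in seq_len(nrow(filt))) {
    x <- filt[ch, ]
    xp <- c(2 * x[1L] - rev(x[2L:(pad + 1L)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1L)]))
    y <- signal::filtfilt(bf, xp)
    filt[ch, ] <- y[(pad + 1L):(pad + n)]
  }
  out <- recording(filt, fs, channel_labels = rec$channel_labels,
                   id = rec$id, t0 = rec$t0)
  attr(out, "band") <- c(low, high)
  out
}

#' Segment a recording into non-overlapping 1-second epochs
#'
#' Epoch `i` (0-based) covers the half-open interval `[i, i+1)` seconds of
#' the window; a trailing partial second is discarded. Concatenating the
#' epochs reproduces the first `floor(duration)` seconds exactly.
#'
#' @param rec A `pges_recording` (duration at least 1 s).
#' @param epoch_length Epoch length in seconds (default 1).
#' @return A `pges_epochs` object: list with `epochs` (channel x epoch x
#'   sample array), `fs`, `epoch_length`, `band` (if the input was
#'   filtered), and `epoch_start` (seconds after seizure end, 0-based).
#' @export
epoch_signal <- function(rec, epoch_length = 1) {
  check_recording(rec, require_montage = FALSE)
  spe <- as.integer(round(rec$fs * epoch_length))
  n_epochs <- ncol(rec$samples) %/% spe
  if (n_epochs < 1L) stop("recording shorter than one epoch")
  arr <- array(rec$samples[, seq_len(n_epochs * spe), drop = FALSE],
               dim = c(nrow(rec$samples), spe, n_epochs))
  arr <- aperm(arr, c(1L, 3L, 2L))  # channel x epoch x sample
  dimnames(arr) <- list(rec$channel_labels, NULL, NULL)
  structure(list(epochs = arr, fs = rec$fs, epoch_length = epoch_length,
                 band = attr(rec, "band"),
                 epoch_start = (seq_len(n_epochs) - 1L) * epoch_length),
            class = "pges_epochs")
}
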