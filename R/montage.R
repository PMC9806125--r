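#' Canonical 18-channel bipolar montage
#'
#' The fixed, ordered set of 18 bipolar scalp-EEG derivations used throughout
#' the pipeline: the left and right temporal chains, the left and right
#' parasagittal chains, and the midline pair. Every [recording()] carries its
#' channels in exactly this order.
#'
#' @return Character vector of 18 bipolar channel labels.
#' @export
#' @examples
#' pges_montage()
pges_montage <- function() {
  c("Fp1-F7", "F7-T7", "T7-P7", "P7-O1",
    "Fp2-F8", "F8-T8", "T8-P8", "P8-O2",
    "Fp1-F3", "F3-C3", "C3-P3", "P3-O1",
    "Fp2-F4", "F4-C4", "C4-P4", "P4-O2",
    "Fz-Cz", "Cz-Pz")
}

#' Multi-channel postictal EEG recording
#'
#' Container for one multi-channel EEG window. Amplitudes are in microvolts;
#' time is measured in seconds relative to the end of the seizure (`t0` is
#' the time of the first sample on that axis, so `t0 = 0` means the window
#' starts at seizure end). Channels are stored channel-major (channels x
#' samples) in the canonical montage order.
#'
#' @param samples Numeric matrix, channels x samples, amplitudes in microvolts.
#' @param fs Sampling frequency in Hz (must be positive).
#' @param channel_labels Channel labels matching the rows of `samples`;
#'   defaults to [pges_montage()].
#' @param id Recording identifier string.
#' @param t0 Time of the first sample in seconds relative to seizure end
#'   (`NA` when the seizure end is not yet known for a raw file).
#' @return An object of class `pges_recording`.
#' @export
recording <- function(samples, fs, channel_labels = pges_montage(),
                      id = "recording", t0 = NA_real_) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.numeric(samples), length(fs) == 1L, fs > 0)
  if (nrow(samples) != length(channel_labels)) {
    stop("samples has ", nrow(samples), " rows but ", length(channel_labels),
         " channel labels were given")
  }
  rownames(samples) <- channel_labels
  structure(list(id = id, samples = samples, fs = fs,
                 channel_labels = channel_labels, t0 = t0),
            class = "pges_recording")
}

#' @export
print.pges_recording <- function(x, ...) {
  cat(sprintf("<pges_recording '%s': %d channels x %d samples, %g Hz, %.1f s>\n",
              x$id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x A `pges_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) ncol(x$samples) / x$fs

# Validate a recording against pipeline assumptions (18 canonical channels).
check_recording <- function(x, require_montage = TRUE) {
  stopifnot(inherits(x, "pges_recording"))
  if (require_montage && !identical(x$channel_labels, pges_montage())) {
    stop("recording '", x$id, "' does not carry the canonical 18-channel montage")
  }
  invisible(x)
}
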