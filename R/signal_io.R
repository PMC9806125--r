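#' Read an EEG recording into the canonical bipolar montage
#'
#' Reads an EDF file and returns a [recording()] whose channels are the 18
#' bipolar derivations of [pges_montage()], in fixed order. Files may store
#' either the bipolar channels directly or referential electrodes, in which
#' case each bipolar channel `X-Y` is derived as `X - Y`. Recordings sampled
#' at a rate other than `target_fs` are resampled (cubic interpolation) so
#' that all downstream window arithmetic can assume one rate.
#'
#' @param path Path to an EDF file.
#' @param montage Ordered bipolar labels to assemble; default [pges_montage()].
#' @param target_fs Sampling rate the pipeline runs at, in Hz (default 200).
#' @return A `pges_recording` with `t0 = NA` (seizure end not yet applied).
#' @export
read_recording <- function(path, montage = pges_montage(), target_fs = 200) {
  edf <- read_edf(path)
  have <- edf$labels
  if (all(montage %in% have)) {
    samples <- edf$samples[match(montage, have), , drop = FALSE]
  } else {
    parts <- strsplit(montage, "-", fixed = TRUE)
    missing <- montage[!vapply(parts, function(p) {
      length(p) == 2L && all(p %in% have)
    }, logical(1L)) & !(montage %in% have)]
    if (length(missing) > 0L) {
      stop("cannot assemble bipolar montage from '", basename(path),
           "'; missing channel(s): ", paste(missing, collapse = ", "))
    }
    samples <- t(vapply(seq_along(montage), function(i) {
      if (montage[i] %in% have) return(edf$samples[match(montage[i], have), ])
      p <- parts[[i]]
      edf$samples[match(p[1L], have), ] - edf$samples[match(p[2L], have), ]
    }, numeric(ncol(edf$samples))))
  }
  fs <- edf$fs
  if (!isTRUE(all.equal(fs, target_fs))) {
    n_new <- round(ncol(samples) / fs * target_fs)
    t_old <- (seq_len(ncol(samples)) - 1L) / fs
    t_new <- (seq_len(n_new) - 1L) / target_fs
    samples <- t(apply(samples, 1L, function(x) {
      stats::spline(t_old, x, xout = t_new, method = "natural")$y
    }))
    fs <- target_fs
  }
  recording(samples, fs, channel_labels = montage,
            id = sub("\\.edf$", "", basename(path), ignore.case = TRUE))
}

#' Write a recording to an EDF file
#'
#' @param rec A `pges_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  check_recording(rec, require_montage = FALSE)
  write_edf(rec$samples, rec$fs, path, labels = rec$channel_labels,
            recording_field = paste("Startdate X", rec$id))
}

#' Create a one-row annotation table
#'
#' Ground-truth annotations for one recording: when the seizure ended (in
#' source-file time), whether PGES was present, and — when annotated — the
#' time of the first intermittent slow wave (equivalently the PGES end), in
#' seconds after seizure end.
#'
#' @param recording_id Identifier matching the recording.
#' @param seizure_end Seizure end in seconds of source-file time.
#' @param has_pges Logical; was PGES present?
#' @param pges_end PGES end / first-ISW time in seconds after seizure end;
#'   `NA` allowed only when `has_pges` is `FALSE`.
#' @return A one-row data frame with class `pges_annotation` retained in
#'   column structure (plain data frame, stable column order).
#' @export
annotation <- function(recording_id, seizure_end, has_pges,
                       pges_end = NA_real_) {
  df <- data.frame(recording_id = as.character(recording_id),
                   seizure_end = as.numeric(seizure_end),
                   has_pges = as.logical(has_pges),
                   pges_end = as.numeric(pges_end),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  needed <- c("recording_id", "seizure_end", "has_pges", "pges_end")
  if (!all(needed %in% names(df))) {
    stop("annotation table must have columns: ", paste(needed, collapse = ", "))
  }
  df <- df[needed]
  bad <- which(df$has_pges & is.na(df$pges_end))
  if (length(bad) > 0L) {
    stop("annotation row(s) ", paste(bad, collapse = ", "),
         " (", paste(df$recording_id[bad], collapse = ", "),
         "): has_pges is TRUE but pges_end is missing")
  }
  neg <- which(!is.na(df$pges_end) & df$pges_end < 0)
  if (length(neg) > 0L) {
    stop("annotation row(s) ", paste(neg, collapse = ", "),
         ": pges_end must be >= 0 seconds")
  }
  df
}

#' Read an annotation table from CSV
#'
#' Expects a header row with columns `recording_id`, `seizure_end`,
#' `has_pges`, `pges_end` (seconds; decimals allowed; `pges_end` empty when
#' not annotated).
#'
#' @param path CSV file path.
#' @return Data frame of validated annotations, one row per recording.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$has_pges <- as.logical(df$has_pges)
  df$pges_end <- suppressWarnings(as.numeric(df$pges_end))
  df$seizure_end <- as.numeric(df$seizure_end)
  validate_annotations(df)
}

#' Write an annotation table to CSV
#' @param ann Annotation data frame (see [annotation()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write.csv(validate_annotations(ann), path, row.names = FALSE, na = "")
  invisible(path)
}
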