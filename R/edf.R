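# Minimal continuous EDF (16-bit) reader and writer. Covers the subset of
# the format the pipeline needs: one contiguous signal set, identical
# record duration for all signals, amplitudes stored against a physical
# min/max in microvolts. Annotation (EDF+) streams are not interpreted.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

# numeric -> 8-char ASCII field, as many significant digits as fit
edf_num <- function(x, width = 8L) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1L, nchar(s) - (nchar(s) - width) - 2L))
  }
  edf_pad(trimws(s), width)
}

#' Write signals to an EDF file
#'
#' Stores a channels x samples matrix as 16-bit EDF. Each channel is scaled
#' to its own physical range, so the round trip is exact up to the format's
#' 16-bit quantization of that range.
#'
#' @param samples Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling frequency in Hz.
#' @param path Output file path.
#' @param labels Channel labels (default rownames of `samples`).
#' @param patient,recording_field Free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(samples, fs, path, labels = rownames(samples),
                      patient = "X", recording_field = "Startdate X") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  ns <- nrow(samples)
  n <- ncol(samples)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  # 1-second records when the length allows, otherwise one long record
  if (n %% fs == 0 && fs == round(fs)) {
    spr <- as.integer(fs); ndr <- as.integer(n / fs); rec_dur <- 1
  } else {
    spr <- n; ndr <- 1L; rec_dur <- n / fs
  }
  pmin <- apply(samples, 1L, min)
  pmax <- apply(samples, 1L, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad(patient, 80L), edf_pad(recording_field, 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L), edf_pad("", 44L),
    edf_pad(ndr, 8L), edf_num(rec_dur), edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width) {
    writeChar(paste0(vapply(f, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(labels, 16L)
  field(rep("", ns), 80L)
  field(rep("uV", ns), 8L)
  field(vapply(pmin, edf_num, ""), 8L)
  field(vapply(pmax, edf_num, ""), 8L)
  field(rep(dmin, ns), 8L)
  field(rep(dmax, ns), 8L)
  field(rep("", ns), 80L)
  field(rep(spr, ns), 8L)
  field(rep("", ns), 32L)

  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(ndr)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((samples[s, idx] - pmin[s]) * gain[s] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `samples` (channels x samples matrix in physical units),
#'   `fs` (Hz), and `labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- as.integer(rd(8L))
  rd(44L)
  ndr <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header in ", path)
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16L)
  fields(80L)
  fields(8L)  # physical dimension
  pmin <- as.numeric(fields(8L))
  pmax <- as.numeric(fields(8L))
  dmin <- as.numeric(fields(8L))
  dmax <- as.numeric(fields(8L))
  fields(80L)
  spr <- as.integer(fields(8L))
  fields(32L)
  seek(con, hdr_bytes)

  out <- matrix(0, nrow = ns, ncol = ndr * spr[1L])
  if (length(unique(spr)) != 1L) {
    stop("EDF files with per-signal sampling rates are not supported: ", path)
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(ndr)) {
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     endian = "little", signed = TRUE)
      out[s, idx] <- (dig - dmin[s]) * gain[s] + pmin[s]
    }
  }
  rownames(out) <- labels
  list(samples = out, fs = spr[1L] / rec_dur, labels = labels)
}
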