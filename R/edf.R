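# Minimal European Data Format (EDF) reader/writer: 16-bit integer samples
# with per-signal physical scaling, 1-s data records. Covers continuous
# single-segment recordings with a common sampling rate across channels,
# which is all this package produces and consumes.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are quantised to 16-bit integers over each channel's physical
#' range (round-trip error is bounded by half a quantisation step). The
#' recording is truncated to whole 1-second data records.
#'
#' @param rec a [new_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ws_recording"))
  edf_write_raw(rec$samples, rec$fs, rec$channels, path)
}

# low-level writer on a bare matrix (also used to craft fixtures at sampling
# rates the Recording container itself refuses)
edf_write_raw <- function(samples, fs, channels, path) {
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  rec <- list(samples = samples, fs = fs, channels = channels)
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one data record (1 s)", call. = FALSE)
  pmin_ <- apply(rec$samples, 1, min); pmax_ <- apply(rec$samples, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field(paste("Startdate 01-JAN-2000", "synthetic"), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig_field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  sig_field(rec$channels, 16)
  sig_field(rep("", ns), 80)
  sig_field(rep("uV", ns), 8)
  sig_field(formatC(pmin_, format = "g", digits = 7), 8)
  sig_field(formatC(pmax_, format = "g", digits = 7), 8)
  sig_field(rep(dmin, ns), 8)
  sig_field(rep(dmax, ns), 8)
  sig_field(rep("", ns), 80)
  sig_field(rep(fs, ns), 8)
  sig_field(rep("", ns), 32)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param segment_kind segment label to attach (default `"interictal"`).
#' @return a [new_recording()] in physical units (uV).
#' @export
read_edf <- function(path, segment_kind = "interictal") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- fields(16); fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1) {
    stop("EDF with per-signal sampling rates is not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      samples[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  if (fs == 256) {
    stop("sampling frequency 256 Hz rejected to harmonize analyses", call. = FALSE)
  }
  new_recording(samples, fs = fs, segment_kind = segment_kind, channels = labels)
}
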