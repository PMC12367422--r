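#' Construct a multichannel iEEG recording object
#'
#' A `ws_recording` bundles a channels-by-samples signal matrix (in microvolts)
#' with its sampling rate, start time, segment label and an optional per-sample
#' wake mask. All downstream detectors operate on this container.
#'
#' @param samples numeric matrix, channels x samples, in microvolts. Row names
#'   (if present) are taken as channel names.
#' @param fs sampling frequency in Hz. Recordings at 256 Hz are rejected;
#'   analyses assume at least 500 Hz.
#' @param t0 start time of the first sample in seconds (default 0). Sample `i`
#'   (0-based) is at time `t0 + i/fs`; intervals are half-open `[start, end)`.
#' @param segment_kind one of `"interictal"`, `"preictal"`, `"ictal"`.
#' @param wake_mask optional logical vector, one entry per sample: `TRUE`
#'   where the signal is awake-eligible. `NULL` until [wake_mask()] is run.
#' @param channels optional character vector of channel names; defaults to row
#'   names or `ch1..chN`.
#' @return an object of class `ws_recording`.
#' @export
new_recording <- function(samples, fs, t0 = 0,
                          segment_kind = c("interictal", "preictal", "ictal"),
                          wake_mask = NULL, channels = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  segment_kind <- match.arg(segment_kind)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (fs < 500) {
    stop("sampling frequency ", fs, " Hz rejected: analyses require fs >= 500 Hz",
         call. = FALSE)
  }
  if (anyNA(samples)) stop("signal contains NA after ingest", call. = FALSE)
  if (is.null(channels)) {
    channels <- rownames(samples)
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(channels) == nrow(samples))
  if (!is.null(wake_mask)) {
    stopifnot(is.logical(wake_mask), length(wake_mask) == ncol(samples))
  }
  rownames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, t0 = t0, segment_kind = segment_kind,
         wake_mask = wake_mask, channels = channels),
    class = "ws_recording"
  )
}

#' @export
print.ws_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$fs
  cat(sprintf("<ws_recording> %d channel(s), %.1f s @ %g Hz, %s\n",
              nrow(x$samples), dur, x$fs, x$segment_kind))
  if (!is.null(x$wake_mask)) {
    cat(sprintf("  wake: %.1f%% of samples\n", 100 * mean(x$wake_mask)))
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `ws_recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Wake duration in minutes
#'
#' Total awake-eligible time per the recording's wake mask (whole recording if
#' no mask has been computed).
#' @param rec a `ws_recording`.
#' @return minutes of wake.
#' @export
wake_minutes <- function(rec) {
  n <- if (is.null(rec$wake_mask)) ncol(rec$samples) else sum(rec$wake_mask)
  n / rec$fs / 60
}

# sample index (1-based) of a time in seconds, clamped to the recording
time_to_index <- function(rec, t, clamp = TRUE) {
  i <- floor((t - rec$t0) * rec$fs) + 1L
  if (clamp) i <- pmin(pmax(i, 1L), ncol(rec$samples))
  as.integer(i)
}

index_to_time <- function(rec, i) rec$t0 + (i - 1L) / rec$fs

#' Validate a channels metadata table
#'
#' Channel tables follow the BIDS-iEEG channels.tsv dialect used throughout
#' the package: one row per electrode contact with millimetre coordinates and
#' gray-matter / seizure-onset-zone / resection flags.
#'
#' @param channels data.frame with columns `name`, `x`, `y`, `z` (mm, finite),
#'   `gray`, `soz`, `resected` (logical or 0/1).
#' @return the validated data.frame with logical flag columns.
#' @export
validate_channels <- function(channels) {
  req <- c("name", "x", "y", "z", "gray", "soz", "resected")
  miss <- setdiff(req, names(channels))
  if (length(miss)) {
    stop("channels table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cc in c("x", "y", "z")) {
    if (!all(is.finite(channels[[cc]]))) {
      stop("channel coordinates must be finite (column ", cc, ")", call. = FALSE)
    }
  }
  for (cc in c("gray", "soz", "resected")) {
    v <- channels[[cc]]
    if (is.numeric(v)) v <- v != 0
    if (!is.logical(v) || anyNA(v)) {
      stop("channel flag column ", cc, " must be logical 0/1", call. = FALSE)
    }
    channels[[cc]] <- v
  }
  channels$name <- as.character(channels$name)
  channels
}

#' Empty detected-event table
#'
#' The canonical event table used by both detectors: one row per detected
#' event with its kind, channel, peak time, polarity and amplitude.
#' @return zero-row data.frame with the event-table schema.
#' @export
empty_events <- function() {
  data.frame(kind = character(0), channel = character(0), peak_t = numeric(0),
              polarity = integer(0), amplitude = numeric(0),
              burst_id = integer(0), stringsAsFactors = FALSE)
}
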