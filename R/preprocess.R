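#' Notch-filter line noise
#'
#' Spectral (frequency-domain) band-stop centred on the mains frequency with
#' bandwidth `line_hz / q`: the Fourier coefficients inside the stop band are
#' zeroed and the signal reconstructed. The filter is exactly zero-phase —
#' event peak latencies, on which all delay statistics depend, are untouched
#' — and exactly idempotent: a second application changes nothing, because
#' the stop band is already empty.
#'
#' @param rec a [new_recording()].
#' @param line_hz mains frequency in Hz (default 60).
#' @param q notch quality factor; stop band = `line_hz / q` Hz wide
#'   (default 30, i.e. a 2-Hz notch at 60 Hz).
#' @return the recording with filtered samples.
#' @export
notch_filter <- function(rec, line_hz = 60, q = 30) {
  stopifnot(inherits(rec, "ws_recording"))
  if (rec$fs <= 2 * line_hz) {
    stop("fs must exceed twice the line frequency", call. = FALSE)
  }
  bw <- line_hz / q
  n <- ncol(rec$samples)
  freqs <- (seq_len(n) - 1) * rec$fs / n
  freqs <- pmin(freqs, rec$fs - freqs)        # two-sided frequency axis
  kill <- abs(freqs - line_hz) <= bw / 2
  for (ch in seq_len(nrow(rec$samples))) {
    X <- stats::fft(rec$samples[ch, ])
    X[kill] <- 0
    rec$samples[ch, ] <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  rec
}

#' Compute the alpha/delta wake mask
#'
#' Awake data are selected by the alpha/delta bandpower ratio: a window is
#' wake iff its 8-12 Hz power exceeds `ratio_threshold` times its 0.5-4 Hz
#' power. The ratio is computed per channel — window band power is the lower
#' quartile of the squared band-passed samples, a robust scale statistic
#' (proportional to mean power for stationary noise) that sparse
#' high-amplitude slow-wave transients, which are themselves wake events,
#' cannot flip to sleep — and a window counts as wake when the median
#' across channels of the per-channel ratio exceeds the threshold. The mask is constant
#' within windows and never alters sample values, only their eligibility.
#'
#' @param rec a [new_recording()].
#' @param win_s window length in seconds (>= 2; default 10).
#' @param ratio_threshold alpha/delta power ratio above which a window counts
#'   as wake (default 1).
#' @return the recording with its `wake_mask` field set.
#' @export
wake_mask <- function(rec, win_s = 10, ratio_threshold = 1) {
  stopifnot(inherits(rec, "ws_recording"))
  if (win_s < 2) stop("win_s must be at least 2 s", call. = FALSE)
  n <- ncol(rec$samples)
  nwin <- round(win_s * rec$fs)
  if (nwin > n) stop("window longer than recording", call. = FALSE)
  nch <- nrow(rec$samples)
  alpha <- delta <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    x <- rec$samples[ch, ]
    alpha[ch, ] <- filt_bandpass(x, rec$fs, 8, 12)^2
    delta[ch, ] <- filt_bandpass(x, rec$fs, 0.5, 4)^2
  }
  starts <- seq(1L, n, by = nwin)
  mask <- logical(n)
  for (s in starts) {
    e <- min(s + nwin - 1L, n)
    ratio <- vapply(seq_len(nch), function(ch)
      stats::quantile(alpha[ch, s:e], 0.25) /
        max(stats::quantile(delta[ch, s:e], 0.25), .Machine$double.eps),
      numeric(1))
    mask[s:e] <- stats::median(ratio) > ratio_threshold
  }
  rec$wake_mask <- mask
  rec
}

#' Drop artifact-laden channels
#'
#' Heuristic channel screen: channels whose signal is flat (successive-sample
#' difference below `flat_eps` uV) for more than `flat_frac` of samples, or
#' whose absolute amplitude exceeds `amp_limit` uV for more than `amp_frac`
#' of samples, are removed.
#'
#' @param rec a [new_recording()].
#' @param channels matching channel table (rows dropped in step).
#' @param flat_frac,flat_eps,amp_limit,amp_frac screen parameters.
#' @return list of the cleaned `recording` and `channels`, plus `dropped`
#'   channel names.
#' @export
drop_artifact_channels <- function(rec, channels = NULL, flat_frac = 0.2,
                                   flat_eps = 1e-3, amp_limit = 1000,
                                   amp_frac = 0.01) {
  stopifnot(inherits(rec, "ws_recording"))
  bad <- vapply(seq_len(nrow(rec$samples)), function(ch) {
    x <- rec$samples[ch, ]
    flat <- mean(abs(diff(x)) < flat_eps)
    hot <- mean(abs(x) > amp_limit)
    flat > flat_frac || hot > amp_frac
  }, logical(1))
  dropped <- rec$channels[bad]
  if (any(bad)) {
    rec$samples <- rec$samples[!bad, , drop = FALSE]
    rec$channels <- rec$channels[!bad]
    if (!is.null(channels)) channels <- channels[!channels$name %in% dropped, ]
    message("dropped ", sum(bad), " artifact channel(s): ",
            paste(dropped, collapse = ", "))
  }
  list(recording = rec, channels = channels, dropped = dropped)
}
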