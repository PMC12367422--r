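#' Detect interictal epileptiform discharges (IEDs)
#'
#' Hilbert-envelope detector: each channel is band-passed to 20-80 Hz
#' (zero-phase 4th-order Butterworth) and the amplitude envelope extracted as
#' the modulus of the analytic signal. Candidate events are supra-threshold
#' excursions of the envelope above `env_factor` (3.5) times its mean over the
#' channel's wake samples; excursions separated by less than `merge_gap_s` are
#' merged before peak picking (ties broken to the earlier sample). A candidate
#' is discarded when the peak amplitude (envelope) of the 5-Hz high-passed
#' raw signal within the excursion falls below `raw_factor` (4) times the
#' mean envelope of that high-passed signal. Both thresholds are ratios to
#' per-channel mean envelopes, so detection is invariant to global rescaling.
#' Only peaks inside the wake mask are returned.
#'
#' @param rec a [new_recording()]; run [wake_mask()] first (a recording with
#'   no mask treats all samples as wake, with a warning).
#' @param env_factor envelope threshold as a multiple of the mean 20-80 Hz
#'   envelope (default 3.5).
#' @param raw_factor amplitude veto as a multiple of the mean envelope of the
#'   5-Hz high-passed signal (default 4).
#' @param merge_gap_s excursions closer than this are merged (default 0.04 s).
#' @param hp_hz high-pass cutoff for the raw-amplitude veto (default 5 Hz,
#'   removing DC offset).
#' @return event data.frame (kind = `"IED"`, channel, peak_t, polarity,
#'   amplitude in uV of the high-passed signal at the peak, burst_id = NA),
#'   sorted by channel then time.
#' @export
detect_ieds <- function(rec, env_factor = 3.5, raw_factor = 4,
                        merge_gap_s = 0.04, hp_hz = 5) {
  stopifnot(inherits(rec, "ws_recording"))
  if (rec$fs < 500) stop("IED detection requires fs >= 500 Hz", call. = FALSE)
  mask <- rec$wake_mask
  if (is.null(mask)) {
    warning("no wake mask on recording; treating all samples as wake")
    mask <- rep(TRUE, ncol(rec$samples))
  }
  if (!any(mask)) {
    warning("empty wake data; no IEDs detected")
    return(empty_events())
  }
  out <- list()
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    if (stats::sd(x) == 0) next  # all-constant channel
    env <- hilbert_envelope(filt_bandpass(x, rec$fs, 20, 80))
    m_env <- mean(env[mask])
    if (m_env == 0) next
    hp <- filt_highpass(x, rec$fs, hp_hz)
    hp_env <- hilbert_envelope(hp)
    m_hp <- mean(hp_env[mask])

    above <- env > env_factor * m_env
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    seg <- cbind(start = starts[r$values], end = ends[r$values])
    # merge excursions separated by < merge_gap_s
    gap <- round(merge_gap_s * rec$fs)
    if (nrow(seg) > 1) {
      merged <- list(seg[1, ])
      for (i in 2:nrow(seg)) {
        last <- merged[[length(merged)]]
        if (seg[i, "start"] - last["end"] < gap) {
          last["end"] <- seg[i, "end"]
          merged[[length(merged)]] <- last
        } else merged[[length(merged) + 1]] <- seg[i, ]
      }
      seg <- do.call(rbind, merged)
    }
    for (i in seq_len(nrow(seg))) {
      idx <- seg[i, "start"]:seg[i, "end"]
      pk <- idx[which.max(env[idx])]       # ties -> earlier sample
      if (!mask[pk]) next                   # wake-only events
      raw_amp <- max(hp_env[idx])
      if (raw_amp < raw_factor * m_hp) next # raw-amplitude veto
      out[[length(out) + 1]] <- data.frame(
        kind = "IED", channel = rec$channels[ch],
        peak_t = index_to_time(rec, pk),
        polarity = as.integer(sign(hp[pk])),
        amplitude = raw_amp, burst_id = NA_integer_)
    }
  }
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$channel, ev$peak_t), ]
  rownames(ev) <- NULL
  ev
}

#' Collapse IED bursts to their first event
#'
#' Sequences of same-channel IEDs whose consecutive inter-peak gaps are below
#' `gap_s` form a burst (gap-based chaining: each event arriving within
#' `gap_s` of the previous one extends the burst). All members share a
#' `burst_id`; only the first event of each burst is retained, so that
#' propagated discharges are not double counted. Idempotent.
#'
#' @param events event data.frame sorted per channel (as from
#'   [detect_ieds()]).
#' @param gap_s chaining gap in seconds (default 0.2).
#' @return the retained events with `burst_id` filled in.
#' @export
collapse_bursts <- function(events, gap_s = 0.2) {
  if (!nrow(events)) return(events)
  events <- events[order(events$channel, events$peak_t), , drop = FALSE]
  new_chan <- !duplicated(events$channel)
  gap <- c(Inf, diff(events$peak_t))
  gap[new_chan] <- Inf
  new_burst <- gap >= gap_s
  events$burst_id <- cumsum(new_burst)
  keep <- events[new_burst, , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
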