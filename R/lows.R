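#' Detect slow half-wave candidates
#'
#' The signal is band-passed to 0.5-4 Hz (zero-phase) and zero-crossings
#' marked; every half-wave between consecutive crossings, of either polarity,
#' whose duration lies in `[min_dur, max_dur]` seconds is a candidate. The
#' half-wave amplitude is the maximum absolute filtered value between its
#' crossings. Candidates whose amplitude is at or below the channel's
#' `percentile` quantile of all its candidate waves are discarded (strictly
#' above the threshold survives), making detection invariant to global
#' rescaling. Only candidates whose peak lies in the wake mask are kept.
#'
#' @param rec a [new_recording()]; run [wake_mask()] first.
#' @param percentile amplitude quantile below-or-at which waves are discarded
#'   (default 0.9, i.e. the 90th percentile per electrode).
#' @param min_dur,max_dur half-wave duration window in seconds
#'   (defaults 0.25 and 1).
#' @param threshold_ref optional named numeric vector of per-channel
#'   amplitude thresholds (uV) computed earlier (e.g. on interictal data) and
#'   applied unchanged instead of recomputing the percentile — used when
#'   comparing preictal with interictal rates.
#' @return data.frame of candidates: channel, start_t, end_t, peak_t,
#'   polarity, amplitude (uV), threshold (the uV cut applied on that
#'   channel); sorted by channel then time.
#' @export
detect_halfwaves <- function(rec, percentile = 0.9, min_dur = 0.25,
                             max_dur = 1, threshold_ref = NULL) {
  stopifnot(inherits(rec, "ws_recording"))
  mask <- rec$wake_mask
  if (is.null(mask)) {
    warning("no wake mask on recording; treating all samples as wake")
    mask <- rep(TRUE, ncol(rec$samples))
  }
  out <- list()
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    lf <- filt_bandpass(x, rec$fs, 0.5, 4)
    zc <- zero_crossings(lf)
    if (length(zc) < 2) next
    dur <- diff(zc) / rec$fs
    ok <- which(dur >= min_dur & dur <= max_dur)
    if (!length(ok)) next
    cand <- lapply(ok, function(i) {
      idx <- (zc[i] + 1L):zc[i + 1L]
      pk <- idx[which.max(abs(lf[idx]))]
      data.frame(channel = rec$channels[ch],
                 start_t = index_to_time(rec, zc[i] + 1L),
                 end_t = index_to_time(rec, zc[i + 1L] + 1L),
                 peak_t = index_to_time(rec, pk),
                 polarity = as.integer(sign(lf[pk])),
                 amplitude = abs(lf[pk]))
    })
    cand <- do.call(rbind, cand)
    thr <- if (!is.null(threshold_ref)) {
      unname(threshold_ref[rec$channels[ch]])
    } else {
      stats::quantile(cand$amplitude, percentile, names = FALSE)  # type 7
    }
    cand$threshold <- thr
    cand <- cand[cand$amplitude > thr, , drop = FALSE]     # strictly above
    if (nrow(cand)) {
      pk_idx <- time_to_index(rec, cand$peak_t)
      cand <- cand[mask[pk_idx], , drop = FALSE]
    }
    if (nrow(cand)) out[[length(out) + 1]] <- cand
  }
  if (!length(out)) {
    return(data.frame(channel = character(0), start_t = numeric(0),
                      end_t = numeric(0), peak_t = numeric(0),
                      polarity = integer(0), amplitude = numeric(0),
                      threshold = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$channel, res$peak_t), ]
  rownames(res) <- NULL
  res
}

#' Discard half-wave candidates near an IED
#'
#' A candidate is removed iff its peak lies within `radius_s` seconds of any
#' detected IED peak on the same channel (post-IED slow deflections are a
#' different electrophysiologic entity and must not contaminate the LoWS set).
#'
#' @param candidates from [detect_halfwaves()].
#' @param ied_events IED event table (after [collapse_bursts()] or not).
#' @param radius_s exclusion radius in seconds (default 1).
#' @return the surviving candidates.
#' @export
exclude_near_ied <- function(candidates, ied_events, radius_s = 1) {
  if (!nrow(candidates) || !nrow(ied_events)) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    it <- ied_events$peak_t[ied_events$channel == candidates$channel[i]]
    !length(it) || all(abs(candidates$peak_t[i] - it) > radius_s)
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gate half-wave candidates on a high-gamma downstate
#'
#' Only waves associated with a downstate — a drop in 45-130 Hz (high-gamma)
#' power — count as LoWS. The gate compares mean HG power (squared Hilbert
#' envelope of the 45-130 Hz band-passed signal) inside the half-wave
#' `[start_t, end_t)` with the mean over two flanking baseline windows at
#' `[-1.5, -0.5]` and `[+0.5, +1.5]` s relative to the peak, and keeps the
#' wave iff the in-wave power is at most `(1 - margin)` times the flanking
#' power. Candidates whose flanks extend past the recording edge are skipped
#' with a message.
#'
#' @param candidates from [exclude_near_ied()].
#' @param rec the same `ws_recording` the candidates came from.
#' @param margin required fractional HG power drop in [0,1); default 0.4
#'   (in-wave power must be below 60% of flanking power, about two standard
#'   errors of the in-wave mean-power estimate: the relative SD of mean band
#'   power over a 0.25-1 s window is `1/sqrt(bandwidth x duration)`, roughly
#'   0.2 at 85 Hz bandwidth). `0` reduces to a strictly-lower criterion.
#' @return event data.frame in the common schema (kind = `"LoWS"`), with
#'   `downstate = TRUE` and the candidate geometry columns retained.
#' @export
downstate_gate <- function(candidates, rec, margin = 0.4) {
  stopifnot(inherits(rec, "ws_recording"))
  if (!nrow(candidates)) {
    out <- cbind(empty_events(), start_t = numeric(0), end_t = numeric(0),
                 downstate = logical(0))
    return(out)
  }
  fs <- rec$fs
  dur <- rec_duration(rec)
  hg_pow <- matrix(NA_real_, nrow(rec$samples), ncol(rec$samples))
  for (ch in seq_len(nrow(rec$samples))) {
    hg_pow[ch, ] <- hilbert_envelope(
      filt_bandpass(rec$samples[ch, ], fs, 45, min(130, fs / 2 - 5)))^2
  }
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(candidates))) {
    ch <- match(candidates$channel[i], rec$channels)
    pk <- candidates$peak_t[i]
    if (pk - 1.5 < rec$t0 || pk + 1.5 > rec$t0 + dur) {
      skipped <- skipped + 1L
      next
    }
    inside <- time_to_index(rec, candidates$start_t[i]):
      (time_to_index(rec, candidates$end_t[i]) - 1L)
    fl1 <- time_to_index(rec, pk - 1.5):time_to_index(rec, pk - 0.5)
    fl2 <- time_to_index(rec, pk + 0.5):time_to_index(rec, pk + 1.5)
    p_in <- mean(hg_pow[ch, inside])
    p_fl <- mean(hg_pow[ch, c(fl1, fl2)])
    if (p_in <= (1 - margin) * p_fl) {
      rows[[length(rows) + 1]] <- data.frame(
        kind = "LoWS", channel = candidates$channel[i], peak_t = pk,
        polarity = candidates$polarity[i],
        amplitude = candidates$amplitude[i], burst_id = NA_integer_,
        start_t = candidates$start_t[i], end_t = candidates$end_t[i],
        downstate = TRUE)
    }
  }
  if (skipped) message(skipped, " candidate(s) skipped: too close to recording edge")
  if (!length(rows)) {
    return(cbind(empty_events(), start_t = numeric(0), end_t = numeric(0),
                 downstate = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$channel, out$peak_t), ]
  rownames(out) <- NULL
  out
}

#' Full LoWS detection chain
#'
#' Half-wave geometry, per-electrode amplitude percentile, 1-s IED exclusion,
#' and the high-gamma downstate gate, in that order. Asserts on every run
#' that the resulting LoWS and IED sets are disjoint in time (> `radius_s`
#' separation per channel) by construction.
#'
#' @inheritParams detect_halfwaves
#' @inheritParams exclude_near_ied
#' @inheritParams downstate_gate
#' @return LoWS event table as from [downstate_gate()].
#' @export
detect_lows <- function(rec, ied_events, percentile = 0.9, radius_s = 1,
                        margin = 0.4, threshold_ref = NULL) {
  cand <- detect_halfwaves(rec, percentile = percentile,
                           threshold_ref = threshold_ref)
  cand <- exclude_near_ied(cand, ied_events, radius_s = radius_s)
  lows <- downstate_gate(cand, rec, margin = margin)
  # disjointness invariant
  if (nrow(lows) && nrow(ied_events)) {
    for (ch in unique(lows$channel)) {
      lt <- lows$peak_t[lows$channel == ch]
      it <- ied_events$peak_t[ied_events$channel == ch]
      if (length(it) && any(vapply(lt, function(t) any(abs(t - it) <= radius_s),
                                   logical(1)))) {
        stop("internal error: LoWS within the IED exclusion radius survived")
      }
    }
  }
  lows
}
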