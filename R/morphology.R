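#' Morphological features of a detected event
#'
#' Amplitude and limb slopes measured on the band-limited waveform each
#' detector operates on (IEDs: the 5-Hz high-passed signal; LoWS: the
#' 0.5-4 Hz signal; `band = "raw"` uses the unfiltered trace). The rising
#' slope runs from the half-maximum crossing on the ascending limb to the
#' peak; the descending slope from the peak to the half-maximum crossing on
#' the descending limb. Events whose half-maximum is not crossed within 1 s
#' of the peak are skipped with a message. Both features scale linearly with
#' the signal, so feature standardisation downstream removes uV units.
#'
#' @param event one event row (with `kind`, `channel`, `peak_t`).
#' @param rec the `ws_recording` the event was detected on.
#' @param band `"auto"` (per-kind default), `"raw"`, `"hp5"` or `"delta"`.
#' @return one-row data.frame: amplitude (uV), rise_slope, fall_slope
#'   (uV/s), true_kind; or `NULL` if skipped.
#' @export
waveform_features <- function(event, rec, band = "auto") {
  stopifnot(inherits(rec, "ws_recording"))
  fs <- rec$fs
  if (event$peak_t - 1 < rec$t0 || event$peak_t + 1 > rec$t0 + rec_duration(rec)) {
    message("event at ", event$peak_t, " s skipped: too close to an edge")
    return(NULL)
  }
  ch <- match(event$channel, rec$channels)
  if (is.na(ch)) stop("unknown channel: ", event$channel, call. = FALSE)
  x <- rec$samples[ch, ]
  if (band == "auto") band <- if (event$kind == "IED") "hp5" else "delta"
  w <- switch(band,
    raw = x,
    hp5 = filt_highpass(x, fs, 5),
    delta = filt_bandpass(x, fs, 0.5, 4),
    stop("unknown band: ", band, call. = FALSE))
  pk0 <- time_to_index(rec, event$peak_t)
  # re-centre to the local extremum within +/-25 ms (filtered peak may be
  # offset from the detector's timestamp by a sample or two)
  win <- max(1L, pk0 - round(0.025 * fs)):min(length(w), pk0 + round(0.025 * fs))
  pk <- win[which.max(abs(w[win]))]
  pol <- sign(w[pk]); if (pol == 0) pol <- 1
  v <- w * pol                       # work on the positive-going lobe
  amp <- v[pk]
  half <- amp / 2
  lim <- round(fs)                   # 1-s search limit

  left <- pk - 1L
  while (left > max(1L, pk - lim) && v[left] > half) left <- left - 1L
  right <- pk + 1L
  while (right < min(length(v), pk + lim) && v[right] > half) right <- right + 1L
  if (v[left] > half || v[right] > half) {
    message("event at ", event$peak_t, " s skipped: half-maximum not crossed within 1 s")
    return(NULL)
  }
  # linear interpolation of the exact half-maximum crossing times
  tl <- left + (half - v[left]) / (v[left + 1L] - v[left])
  tr <- right - (half - v[right]) / (v[right - 1L] - v[right])
  rise <- (amp - half) / ((pk - tl) / fs)
  fall <- (amp - half) / ((tr - pk) / fs)
  data.frame(amplitude = amp, rise_slope = rise, fall_slope = fall,
             true_kind = event$kind)
}

#' Feature tables for a set of events
#'
#' @param events event table (rows from both detectors).
#' @param rec the recording.
#' @inheritParams waveform_features
#' @return data.frame of features, one row per non-skipped event.
#' @export
waveform_feature_table <- function(events, rec, band = "auto") {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    f <- suppressMessages(waveform_features(events[i, ], rec, band = band))
    if (!is.null(f)) {
      f$channel <- events$channel[i]
      f$peak_t <- events$peak_t[i]
    }
    f
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(amplitude = numeric(0),
                                      rise_slope = numeric(0),
                                      fall_slope = numeric(0),
                                      true_kind = character(0),
                                      channel = character(0),
                                      peak_t = numeric(0))
  rownames(out) <- NULL
  out
}

#' Morphological separability of IEDs and LoWS by clustering
#'
#' Per patient: features (amplitude, rising slope, descending slope) are
#' standardised and partitioned into 2 clusters by k-means (20 restarts,
#' seeded); clusters are labelled by majority true kind and the 2x2
#' cluster-by-kind table summarised as an odds ratio (Haldane-Anscombe +0.5
#' correction when any cell is zero). An OR above 1 means the two event
#' types occupy separable regions of feature space. At cohort level a
#' two-sided one-sample Wilcoxon signed-rank test compares the per-patient
#' ORs against 1 (chance).
#'
#' @param feature_tables named list (one element per patient) of feature
#'   data.frames from [waveform_feature_table()].
#' @param min_events minimum events of each kind per patient (default 10);
#'   patients below it, or with zero-variance features, are excluded with a
#'   message.
#' @param seed seed for the k-means restarts.
#' @return list: `per_patient` (data.frame patient, odds_ratio, n_ied,
#'   n_lows), `median_or`, `wilcoxon_p`.
#' @export
cluster_separability <- function(feature_tables, min_events = 10, seed = 1L) {
  ors <- list()
  for (p in names(feature_tables)) {
    ft <- feature_tables[[p]]
    n_ied <- sum(ft$true_kind == "IED"); n_lows <- sum(ft$true_kind == "LoWS")
    if (n_ied < min_events || n_lows < min_events) {
      message("patient ", p, " excluded: fewer than ", min_events,
              " events of each kind")
      next
    }
    X <- scale(as.matrix(ft[, c("amplitude", "rise_slope", "fall_slope")]))
    if (any(!is.finite(X))) {
      message("patient ", p, " excluded: degenerate (zero-variance) features")
      next
    }
    km <- with_seed(seed, stats::kmeans(X, centers = 2, nstart = 20))
    is_ied <- ft$true_kind == "IED"
    # orient cluster labels by majority: cluster with more IEDs is "IED"
    ied_cluster <- which.max(c(sum(is_ied & km$cluster == 1),
                               sum(is_ied & km$cluster == 2)))
    tab <- matrix(c(
      sum(is_ied & km$cluster == ied_cluster),
      sum(is_ied & km$cluster != ied_cluster),
      sum(!is_ied & km$cluster == ied_cluster),
      sum(!is_ied & km$cluster != ied_cluster)), 2, 2)
    if (any(tab == 0)) tab <- tab + 0.5       # Haldane-Anscombe
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    ors[[length(ors) + 1]] <- data.frame(patient = p, odds_ratio = or,
                                         n_ied = n_ied, n_lows = n_lows)
  }
  if (!length(ors)) stop("no patient had enough events for clustering", call. = FALSE)
  per_patient <- do.call(rbind, ors)
  wt <- stats::wilcox.test(per_patient$odds_ratio, mu = 1, exact = FALSE)
  list(per_patient = per_patient,
       median_or = stats::median(per_patient$odds_ratio),
       wilcoxon_p = wt$p.value)
}
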