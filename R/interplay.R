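#' Per-channel event rates
#'
#' Rates are events per minute of wake, separately per event kind. Channels
#' with zero wake time are excluded with a message.
#'
#' @param events event table with columns `channel`, `kind` (and optionally
#'   `patient`).
#' @param wake_min wake minutes: a single number applying to all channels, or
#'   a named vector per channel.
#' @param channels optional channel table ([validate_channels()]); its `soz`
#'   and `resected` flags are carried through and channels absent from
#'   `events` get rate 0.
#' @return data.frame: channel, rate_ied, rate_lows (per wake minute), plus
#'   `soz`/`resected` when `channels` is given.
#' @export
event_rates <- function(events, wake_min, channels = NULL) {
  chan_names <- if (!is.null(channels)) channels$name else unique(events$channel)
  wm <- if (length(wake_min) == 1) setNames(rep(wake_min, length(chan_names)), chan_names)
        else wake_min[chan_names]
  bad <- names(wm)[!is.finite(wm) | wm <= 0]
  if (length(bad)) {
    message("excluding channel(s) with zero wake time: ", paste(bad, collapse = ", "))
    chan_names <- setdiff(chan_names, bad)
  }
  out <- data.frame(
    channel = chan_names,
    rate_ied = vapply(chan_names, function(ch)
      sum(events$channel == ch & events$kind == "IED") / wm[ch], numeric(1)),
    rate_lows = vapply(chan_names, function(ch)
      sum(events$channel == ch & events$kind == "LoWS") / wm[ch], numeric(1)),
    row.names = NULL)
  if (!is.null(channels)) {
    out$soz <- channels$soz[match(out$channel, channels$name)]
    out$resected <- channels$resected[match(out$channel, channels$name)]
  }
  out
}

#' Pairwise delays between IEDs and the next LoWS (or vice versa)
#'
#' For direction `"ied2lows"`, every IED is paired with the next LoWS peak on
#' the same channel; IEDs with no later LoWS are censored. `"lows2ied"` is
#' symmetric. When `segments` (a two-column matrix/data.frame of half-open
#' `[start, end)` wake-segment bounds) is supplied, pairs whose two events
#' fall in different segments are censored.
#'
#' @param ieds,lows event tables with `channel` and `peak_t`.
#' @param direction `"ied2lows"` or `"lows2ied"`.
#' @param segments optional segment bounds for boundary censoring.
#' @return data.frame: channel, direction, from_t, to_t, raw_delay (s).
#' @export
pairwise_delays <- function(ieds, lows, direction = c("ied2lows", "lows2ied"),
                            segments = NULL) {
  direction <- match.arg(direction)
  src <- if (direction == "ied2lows") ieds else lows
  dst <- if (direction == "ied2lows") lows else ieds
  out <- list()
  for (ch in unique(src$channel)) {
    st <- sort(src$peak_t[src$channel == ch])
    dt <- sort(dst$peak_t[dst$channel == ch])
    if (!length(st) || !length(dt)) next
    # index of first target strictly after each source event
    pos <- findInterval(st, dt) + 1L
    ok <- pos <= length(dt)
    # guard exact ties: require strictly later target
    ok[ok] <- dt[pos[ok]] > st[ok]
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      channel = ch, direction = direction,
      from_t = st[ok], to_t = dt[pos[ok]],
      raw_delay = dt[pos[ok]] - st[ok])
  }
  if (!length(out)) {
    return(data.frame(channel = character(0), direction = character(0),
                      from_t = numeric(0), to_t = numeric(0),
                      raw_delay = numeric(0)))
  }
  res <- do.call(rbind, out)
  if (!is.null(segments)) {
    seg <- as.matrix(segments)
    seg_of <- function(t) {
      k <- findInterval(t, seg[, 1])
      k[k > 0 & t >= seg[k, 2]] <- NA  # fell in a gap
      k[k == 0] <- NA
      k
    }
    keep <- !is.na(seg_of(res$from_t)) & seg_of(res$from_t) == seg_of(res$to_t)
    keep[is.na(keep)] <- FALSE
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Incidence-corrected delays
#'
#' Waiting times depend mechanically on how often the target event occurs; a
#' channel with many LoWS has short IED-to-LoWS delays by chance alone. The
#' corrected delay divides the raw delay by the expected waiting time under a
#' homogeneous-rate assumption (1 / target-event rate), giving a
#' dimensionless value whose chance level is 1 and which is invariant to
#' joint rescaling of the time axis and rates. For a homogeneous Poisson
#' target train the corrected delay is Exp(1): its per-channel median
#' converges to log(2).
#'
#' @param records from [pairwise_delays()].
#' @param rates from [event_rates()] (rates per minute).
#' @return the records with a `corrected_delay` column added; records on
#'   channels with zero target rate are censored (dropped) with a message.
#' @export
corrected_delays <- function(records, rates) {
  if (!nrow(records)) {
    records$corrected_delay <- numeric(0)
    return(records)
  }
  target <- ifelse(records$direction == "ied2lows", "rate_lows", "rate_ied")
  idx <- match(records$channel, rates$channel)
  if (anyNA(idx)) stop("rates missing for some channels", call. = FALSE)
  rate_per_s <- ifelse(target == "rate_lows", rates$rate_lows[idx],
                       rates$rate_ied[idx]) / 60
  zero <- rate_per_s <= 0
  if (any(zero)) {
    message("censoring ", sum(zero), " record(s) on channels with zero target rate")
  }
  records$corrected_delay <- records$raw_delay * rate_per_s
  out <- records[!zero, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patient-level delay summaries by resection status
#'
#' Channel-level median corrected delay (robust to the heavy right tail of
#' waiting times), then the mean across channels within the resected and
#' non-resected groups. Patients lacking a channel in either group are
#' excluded with a message.
#'
#' @param records corrected delay records ([corrected_delays()]), one
#'   direction at a time; may carry a `patient` column (single patient
#'   assumed otherwise).
#' @param channels channel table with `name`, `resected` (and `patient` when
#'   `records` has one).
#' @return data.frame: patient, direction, resected_mean, nonresected_mean,
#'   n_channels_res, n_channels_non.
#' @export
aggregate_by_resection <- function(records, channels) {
  if (!nrow(records)) {
    return(data.frame(patient = character(0), direction = character(0),
                      resected_mean = numeric(0), nonresected_mean = numeric(0),
                      n_channels_res = integer(0), n_channels_non = integer(0)))
  }
  if (is.null(records$patient)) records$patient <- "P01"
  if (is.null(channels$patient)) channels$patient <- "P01"
  out <- list()
  for (p in unique(records$patient)) {
    rp <- records[records$patient == p, ]
    cp <- channels[channels$patient == p, ]
    for (d in unique(rp$direction)) {
      rd <- rp[rp$direction == d, ]
      med <- tapply(rd$corrected_delay, rd$channel, stats::median)
      res_flag <- cp$resected[match(names(med), cp$name)]
      if (!any(res_flag, na.rm = TRUE) || !any(!res_flag, na.rm = TRUE)) {
        message("patient ", p, " excluded: no channels in one resection group")
        next
      }
      out[[length(out) + 1]] <- data.frame(
        patient = p, direction = d,
        resected_mean = mean(med[which(res_flag)]),
        nonresected_mean = mean(med[which(!res_flag)]),
        n_channels_res = sum(res_flag, na.rm = TRUE),
        n_channels_non = sum(!res_flag, na.rm = TRUE))
    }
  }
  if (!length(out)) {
    return(data.frame(patient = character(0), direction = character(0),
                      resected_mean = numeric(0), nonresected_mean = numeric(0),
                      n_channels_res = integer(0), n_channels_non = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long table of preictal vs interictal event rates by region
#'
#' SOZ membership follows the 10-mm rule: a channel belongs to the SOZ iff it
#' lies within 10 mm Euclidean distance of any seizure-onset channel of the
#' same patient. The preictal period runs from the seizure-file start to 10 s
#' before onset (seizures with a shorter preictal segment are skipped);
#' interictal segments closer than 2 h to any seizure onset are dropped.
#' Rates are events per minute, averaged across a patient's channels within
#' each region.
#'
#' @param events data.frame: patient, segment_id, channel, kind, peak_t
#'   (absolute seconds).
#' @param segments data.frame: patient, segment_id, kind
#'   (`"interictal"`/`"seizure"`), start, end, onset_t, onset_channel.
#' @param channels data.frame: patient, name, x, y, z.
#' @param soz_radius_mm SOZ distance rule in mm (default 10).
#' @param preictal_gap_s excluded window before onset in seconds (default 10).
#' @param interictal_clear_s required clearance of interictal data from any
#'   seizure in seconds (default 7200).
#' @return long data.frame: patient, region (`SOZ`/`extraSOZ`), period
#'   (`interictal`/`preictal`), event (`IED`/`LoWS`), rate (per minute).
#' @export
preictal_contrast_table <- function(events, segments, channels,
                                    soz_radius_mm = 10, preictal_gap_s = 10,
                                    interictal_clear_s = 7200) {
  rows <- list()
  for (p in unique(segments$patient)) {
    sp <- segments[segments$patient == p, ]
    cp <- channels[channels$patient == p, ]
    ep <- events[events$patient == p, ]
    onset_names <- unique(stats::na.omit(sp$onset_channel))
    if (!length(onset_names)) next
    if (!all(onset_names %in% cp$name)) {
      stop("onset channel(s) without coordinates for patient ", p, call. = FALSE)
    }
    oc <- as.matrix(cp[match(onset_names, cp$name), c("x", "y", "z")])
    xyz <- as.matrix(cp[, c("x", "y", "z")])
    dmin <- apply(oc, 1, function(o) sqrt(colSums((t(xyz) - o)^2)))
    soz <- apply(as.matrix(dmin), 1, min) < soz_radius_mm
    names(soz) <- cp$name
    onsets <- stats::na.omit(sp$onset_t)

    windows <- list()
    for (i in seq_len(nrow(sp))) {
      if (sp$kind[i] == "seizure") {
        pe <- sp$onset_t[i] - preictal_gap_s
        if (pe - sp$start[i] < preictal_gap_s) {
          message("patient ", p, ": seizure ", sp$segment_id[i],
                  " skipped (preictal segment too short)")
          next
        }
        windows[[length(windows) + 1]] <-
          list(period = "preictal", lo = sp$start[i], hi = pe)
      } else {
        if (length(onsets) && min(abs(c(sp$start[i], sp$end[i]) - onsets)) <
            interictal_clear_s) {
          message("patient ", p, ": interictal segment ", sp$segment_id[i],
                  " dropped (< 2 h from a seizure)")
          next
        }
        windows[[length(windows) + 1]] <-
          list(period = "interictal", lo = sp$start[i], hi = sp$end[i])
      }
    }
    for (w in windows) {
      minutes <- (w$hi - w$lo) / 60
      for (region in c("SOZ", "extraSOZ")) {
        chs <- cp$name[if (region == "SOZ") soz else !soz]
        if (!length(chs)) next
        for (kind in c("IED", "LoWS")) {
          per_ch <- vapply(chs, function(ch)
            sum(ep$channel == ch & ep$kind == kind &
                  ep$peak_t >= w$lo & ep$peak_t < w$hi) / minutes, numeric(1))
          rows[[length(rows) + 1]] <- data.frame(
            patient = p, region = region, period = w$period, event = kind,
            rate = mean(per_ch))
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  # average multiple windows of the same period
  agg <- stats::aggregate(rate ~ patient + region + period + event, res, mean)
  agg[order(agg$patient, agg$event, agg$region, agg$period), ]
}
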