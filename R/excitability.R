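#' Event-locked high-gamma time-frequency map
#'
#' Hanning-taper sliding-window spectral estimate of 45-130 Hz power in a
#' window of `half_window` seconds either side of an event peak. Windows are
#' 0.2 s with 90% overlap (5-Hz frequency resolution), which resolves the
#' +/-0.05 s readout used by [ied_excitability()].
#'
#' @param rec a [new_recording()].
#' @param event_t event peak time in seconds.
#' @param channel channel name.
#' @param half_window half window length in seconds (default 3).
#' @param fmin,fmax frequency band in Hz (default 45-130).
#' @return list with `power` (freq x time matrix), `freqs` (Hz) and `times`
#'   (s, relative to the event peak), or `NULL` with a message when the event
#'   is closer than `half_window` to a recording edge.
#' @export
hg_power_timecourse <- function(rec, event_t, channel, half_window = 3,
                                fmin = 45, fmax = 130) {
  stopifnot(inherits(rec, "ws_recording"))
  fmax <- min(fmax, rec$fs / 2 - 5)
  if (event_t - half_window < rec$t0 ||
      event_t + half_window > rec$t0 + rec_duration(rec)) {
    message("event at ", event_t, " s skipped: within ", half_window,
            " s of a recording edge")
    return(NULL)
  }
  ch <- match(channel, rec$channels)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  i0 <- time_to_index(rec, event_t - half_window)
  i1 <- time_to_index(rec, event_t + half_window)
  x <- rec$samples[ch, i0:i1]
  tf <- stft_power(x, rec$fs, win_s = 0.2, fmin = fmin, fmax = fmax)
  tf$times <- tf$times + index_to_time(rec, i0) - event_t
  tf
}

#' IED-locked high-gamma excitability samples
#'
#' For each IED, high-gamma (45-130 Hz) power is read out in +/-0.05 s around
#' the peak from the Hanning-taper time-frequency map, log-transformed, and
#' normalised by subtracting the log of baseline HG power over [-3, -1] s of
#' the same window (an epoch outside both the IED and its 1-s LoWS exclusion
#' zone). The delay since the last same-channel LoWS peak is attached; IEDs
#' with no preceding LoWS in the same wake segment, or closer than 3 s to a
#' recording edge, are censored.
#'
#' @param rec a [new_recording()].
#' @param ied_events IED events (after [collapse_bursts()]).
#' @param lows_events LoWS events from [detect_lows()].
#' @param patient optional patient id attached to every sample.
#' @param log_base base of the log-transform (default `exp(1)`).
#' @return data.frame of samples: patient, channel, ied_peak_t, ied_hg
#'   (log-power, baseline-normalised, unitless), delay_since_lows (s).
#' @export
ied_excitability <- function(rec, ied_events, lows_events, patient = "P01",
                             log_base = exp(1)) {
  stopifnot(inherits(rec, "ws_recording"))
  out <- list()
  for (i in seq_len(nrow(ied_events))) {
    ch <- ied_events$channel[i]
    t <- ied_events$peak_t[i]
    lt <- lows_events$peak_t[lows_events$channel == ch & lows_events$peak_t < t]
    if (!length(lt)) next                       # censored: no preceding LoWS
    delay <- t - max(lt)
    if (!is.null(rec$wake_mask)) {
      # censor delays that cross a wake-segment boundary
      i0 <- time_to_index(rec, max(lt)); i1 <- time_to_index(rec, t)
      if (!all(rec$wake_mask[i0:i1])) next
    }
    tf <- suppressMessages(hg_power_timecourse(rec, t, ch))
    if (is.null(tf)) next                       # edge violation
    centre <- tf$times >= -0.05 & tf$times <= 0.05
    base <- tf$times >= -3 & tf$times <= -1
    if (!any(centre) || !any(base)) next
    hg_c <- mean(tf$power[, centre])
    hg_b <- mean(tf$power[, base])
    out[[length(out) + 1]] <- data.frame(
      patient = patient, channel = ch, ied_peak_t = t,
      ied_hg = (log(hg_c) - log(hg_b)) / log(log_base),
      delay_since_lows = delay)
  }
  if (!length(out)) {
    warning("no excitability samples (no LoWS preceding any IED)")
    return(data.frame(patient = character(0), channel = character(0),
                      ied_peak_t = numeric(0), ied_hg = numeric(0),
                      delay_since_lows = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mixed-effects fit of excitability on delay since the last LoWS
#'
#' Fits `ied_hg ~ 1 + delay + (1 + delay | patient)` by REML and returns the
#' fixed-effect slope with its Satterthwaite omnibus F test. Singular fits
#' are refitted with the random slope dropped and flagged.
#'
#' @param samples data.frame from [ied_excitability()] (columns `patient`,
#'   `ied_hg`, `delay_since_lows`), pooled across patients.
#' @return a `ws_fit` list: `term`, `estimate`, `se`, `ci` (95% Wald),
#'   `F`, `df_num`, `df_den`, `p`, `singular` flag and the underlying
#'   `lmerMod` in `$fit`.
#' @export
fit_delay_excitability <- function(samples) {
  if (length(unique(samples$patient)) < 2) {
    stop("at least 2 patients are required for the random-effects structure",
         call. = FALSE)
  }
  samples$delay <- samples$delay_since_lows
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(ied_hg ~ 1 + delay + (1 + delay | patient), data = samples,
                   REML = TRUE)))
  singular <- lme4::isSingular(fit)
  if (singular) {
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(ied_hg ~ 1 + delay + (1 | patient), data = samples,
                     REML = TRUE)))
  }
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  est <- lme4::fixef(fit)["delay"]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))["delay"]
  df <- an["delay", "DenDF"]
  structure(list(
    term = "delay",
    estimate = unname(est),
    se = unname(se),
    ci = unname(est + c(-1, 1) * stats::qt(0.975, df) * se),
    F = an["delay", "F value"],
    df_num = an["delay", "NumDF"],
    df_den = df,
    p = an["delay", "Pr(>F)"],
    singular = singular,
    fit = fit
  ), class = "ws_fit")
}

#' @export
print.ws_fit <- function(x, ...) {
  cat(sprintf("<ws_fit> %s: estimate %.4g, F[%g, %.2f] = %.4g, p = %.4g%s\n",
              x$term, x$estimate, x$df_num, x$df_den, x$F, x$p,
              if (isTRUE(x$singular)) " (singular random-effect fit)" else ""))
  invisible(x)
}

#' Write a model fit as JSON
#'
#' @param fit a `ws_fit` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- fit[setdiff(names(fit), "fit")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
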