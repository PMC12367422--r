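# Shared fixtures, built once per test run and cached. All synthetic; no
# data files are read.

.fx <- new.env(parent = emptyenv())

# small simulated recording with ground truth and both detector outputs
fx_small_pipeline <- function() {
  if (is.null(.fx$small)) {
    cfg <- sim_config(n_channels = 6, duration = 360, seed = 42)
    inj <- inject_events(make_background(cfg), cfg)
    rec <- wake_mask(notch_filter(inj$recording))
    ied <- collapse_bursts(detect_ieds(rec))
    lows <- suppressMessages(detect_lows(rec, ied))
    .fx$small <- list(cfg = cfg, truth = inj$truth, rec = rec,
                      ied = ied, lows = lows)
  }
  .fx$small
}

# fraction of truth events of `kind` matched by a detection within `tol` s
recall_against_truth <- function(events, truth, kind, tol) {
  tr <- truth[truth$kind == kind, ]
  if (!nrow(tr)) return(NA_real_)
  mean(vapply(seq_len(nrow(tr)), function(i)
    any(events$channel == tr$channel[i] &
          abs(events$peak_t - tr$peak_t[i]) < tol), logical(1)))
}

# detections not matching any truth event of `kind` within `tol` s
false_positives <- function(events, truth, kind, tol) {
  ev <- events[events$kind == kind, ]
  if (!nrow(ev)) return(0L)
  tr <- truth[truth$kind == kind, ]
  sum(!vapply(seq_len(nrow(ev)), function(i)
    any(tr$channel == ev$channel[i] &
          abs(tr$peak_t - ev$peak_t[i]) < tol), logical(1)))
}

# a recording holding a single waveform on one channel, zero elsewhere
fx_waveform_recording <- function(wave, at_s = 2, fs = 512, dur_s = 6) {
  x <- numeric(fs * dur_s)
  i0 <- round(at_s * fs) - floor(length(wave) / 2)
  x[i0:(i0 + length(wave) - 1)] <- wave
  new_recording(matrix(x, nrow = 1), fs = fs, channels = "c1")
}

# delay-vs-excitability samples simulated directly at the sample level
fx_excitability_samples <- function(slope, n_pat = 8, n_per = 40,
                                    sd_int = 0.3, sd_slope = 0.05,
                                    sd_noise = 0.5) {
  do.call(rbind, lapply(seq_len(n_pat), function(p) {
    u <- stats::rnorm(1, 0, sd_int)
    v <- stats::rnorm(1, 0, sd_slope)
    delay <- stats::rexp(n_per, 1 / 15) + 1
    data.frame(patient = sprintf("P%02d", p),
               ied_hg = 0.2 + u + (slope + v) * delay +
                 stats::rnorm(n_per, 0, sd_noise),
               delay_since_lows = delay)
  }))
}

# patient-level delay-ratio metrics from a simulated cohort
fx_cohort_metrics <- function(cohort) {
  tab <- cohort_model_table(cohort, "delay")
  agg <- do.call(rbind, lapply(split(tab, tab$patient), function(d)
    data.frame(patient = d$patient[1], direction = "ied2lows",
               resected_mean = d$value[d$resected],
               nonresected_mean = d$value[!d$resected])))
  m <- patient_ratio_metric(agg)
  m$good <- cohort$patients$good[match(m$patient, cohort$patients$patient)]
  m
}
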