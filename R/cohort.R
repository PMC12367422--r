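#' Specification of a simulated surgical cohort
#'
#' Defaults emulate the published cohort's composition: 55 patients, a good
#' (Engel I-II) outcome prevalence near 3/4, roughly one channel in five
#' resected, and a plantable outcome-by-resection interaction on the
#' incidence-corrected IED-to-LoWS delay.
#'
#' @param n_patients number of patients.
#' @param engel_distribution named probabilities over Engel classes I-IV
#'   (must sum to 1).
#' @param frac_resected fraction of channels flagged resected, in (0,1).
#'   Seizure-onset-zone channels are resected preferentially.
#' @param planted_interaction effect size of the outcome-by-resection
#'   interaction: on resected channels the mean corrected IED-to-LoWS delay is
#'   multiplied by `1 + planted_interaction * (engel_linear - 2.5)`, so that
#'   good-outcome patients (Engel I) have shorter, and poor-outcome patients
#'   (Engel IV) longer, delays in resected tissue than elsewhere. `0` plants
#'   no effect (null cohort).
#' @param seed integer seed.
#' @return a `ws_cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 55,
                        engel_distribution = c(I = 0.62, II = 0.14, III = 0.15, IV = 0.09),
                        frac_resected = 0.2,
                        planted_interaction = 0.25,
                        seed = 1L) {
  if (abs(sum(engel_distribution) - 1) > 1e-8) {
    stop("engel_distribution probabilities must sum to 1", call. = FALSE)
  }
  if (frac_resected <= 0 || frac_resected >= 1) {
    stop("frac_resected must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    engel_distribution = engel_distribution,
    frac_resected = frac_resected,
    planted_interaction = planted_interaction,
    seed = as.integer(seed)
  ), class = "ws_cohort_spec")
}

# random channel geometry: contacts in a 60-mm cube, one onset contact,
# SOZ = contacts within 10 mm of it
make_channel_table <- function(n_channels, frac_resected) {
  xyz <- matrix(stats::runif(3 * n_channels, 0, 60), ncol = 3)
  onset <- sample.int(n_channels, 1)
  d <- sqrt(colSums((t(xyz) - xyz[onset, ])^2))
  soz <- d < 10
  n_res <- max(1L, round(frac_resected * n_channels))
  # resection preferentially covers the SOZ
  res_idx <- unique(c(which(soz), sample(setdiff(seq_len(n_channels), which(soz)))))
  resected <- seq_len(n_channels) %in% res_idx[seq_len(min(n_res, length(res_idx)))]
  data.frame(name = sprintf("ch%02d", seq_len(n_channels)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             gray = TRUE, soz = soz, resected = resected,
             onset = seq_len(n_channels) == onset)
}

# simulate one channel's event log: IEDs as Poisson; LoWS as background
# Poisson, with (optionally) each IED's waiting time to the next LoWS drawn
# from the delay law scaled by `mult` (background waves inside the drawn gap
# are removed, one wave is placed at its end)
simulate_channel_events <- function(duration, ied_rate, lows_rate, delay_law, mult) {
  ied <- poisson_refractory(ied_rate / 60, duration)
  lows <- poisson_refractory(lows_rate / 60, duration, refractory = 0)
  if (!identical(delay_law$dist, "none") && length(ied)) {
    chance_mean <- 60 / lows_rate
    for (t in ied) {
      d <- draw_delay(delay_law, 1, mean_default = chance_mean) * mult
      lows <- lows[lows <= t | lows > t + d]
      if (t + d < duration) lows <- c(lows, t + d)
    }
    lows <- sort(lows)
  }
  list(ied = ied, lows = lows)
}

#' Simulate a surgical cohort with ground-truth event logs
#'
#' Generates, per patient: a channel table (3-D coordinates, gray/SOZ/resected
#' flags, the seizure-onset contact), an Engel/ILAE outcome record, and
#' per-channel IED and LoWS event logs over `config$duration` seconds. The
#' outcome-by-resection interaction of `spec$planted_interaction` is planted
#' on the IED-to-next-LoWS waiting times of resected channels. Event logs are
#' generated directly (no signal synthesis), which is what the delay,
#' mixed-model and classifier stages consume; use [make_background()] and
#' [inject_events()] when signal-level detection is under study.
#'
#' @param spec a [cohort_spec()].
#' @param config a [sim_config()]; `n_channels`, `duration`, `ied_rate`,
#'   `lows_rate` and `delay_law` are used. Set
#'   `delay_law = list(dist = "none")` for fully independent Poisson trains.
#' @param require_classes error if fewer than 2 patients per outcome class
#'   were drawn (the patient-level classifier is untrainable below that);
#'   set `FALSE` for calibration loops that do not train a classifier.
#' @return list with data.frames `patients` (patient, engel_class,
#'   engel_linear, ilae, good, lesional, therapy), `channels` (patient +
#'   channel table columns), `events` (patient, channel, kind, peak_t) and
#'   scalar `wake_minutes` per recording.
#' @export
simulate_cohort <- function(spec, config = sim_config(), require_classes = TRUE) {
  stopifnot(inherits(spec, "ws_cohort_spec"), inherits(config, "ws_sim_config"))
  with_seed(spec$seed, {
    classes <- names(spec$engel_distribution)
    engel <- sample(classes, spec$n_patients, replace = TRUE,
                    prob = spec$engel_distribution)
    good <- engel %in% c("I", "II")
    if (require_classes && (sum(good) < 2 || sum(!good) < 2)) {
      stop("fewer than 2 patients per outcome class: classifier untrainable",
           call. = FALSE)
    }
    patients <- data.frame(
      patient = sprintf("P%02d", seq_len(spec$n_patients)),
      engel_class = engel,
      engel_linear = engel_linearize(engel),
      ilae = engel_linearize(engel) + sample(0:1, spec$n_patients, TRUE),
      good = good,
      lesional = stats::runif(spec$n_patients) < 0.5,
      therapy = sample(c("resection", "ablation"), spec$n_patients, TRUE,
                       prob = c(0.6, 0.4))
    )
    chans <- list(); evts <- list()
    for (p in seq_len(spec$n_patients)) {
      ct <- make_channel_table(config$n_channels, spec$frac_resected)
      ct$patient <- patients$patient[p]
      chans[[p]] <- ct
      for (ci in seq_len(nrow(ct))) {
        mult <- 1
        if (ct$resected[ci]) {
          mult <- 1 + spec$planted_interaction * (patients$engel_linear[p] - 2.5)
          mult <- max(mult, 0.05)
        }
        ev <- simulate_channel_events(config$duration, config$ied_rate,
                                      config$lows_rate, config$delay_law, mult)
        evts[[length(evts) + 1]] <- data.frame(
          patient = patients$patient[p], channel = ct$name[ci],
          kind = rep(c("IED", "LoWS"), c(length(ev$ied), length(ev$lows))),
          peak_t = c(ev$ied, ev$lows))
      }
    }
    events <- do.call(rbind, evts)
    events <- events[order(events$patient, events$channel, events$peak_t), ]
    rownames(events) <- NULL
    list(patients = patients,
         channels = do.call(rbind, chans),
         events = events,
         wake_minutes = config$duration / 60)
  })
}

#' Simulate per-channel event logs around seizures
#'
#' Produces interictal segments (sampled well away from seizures) and seizure
#' files with a marked onset, with per-channel event rates that emulate the
#' reported preictal dynamics: IED rates elevated inside the seizure-onset
#' zone but flat across periods, LoWS rates rising before seizures, more so
#' outside the SOZ.
#'
#' @param n_patients patients to simulate.
#' @param n_channels channels per patient.
#' @param interictal_minutes wake minutes of interictal data per patient.
#' @param preictal_s seconds from seizure-file start to seizure onset
#'   (the last 10 s before onset are excluded by the analysis).
#' @param rates baseline interictal rates per minute:
#'   `list(ied_in, ied_out, lows_in, lows_out)` for SOZ / extra-SOZ channels.
#' @param preictal_mult multiplicative preictal rate changes, same structure.
#' @param seed integer seed.
#' @return list of data.frames `channels` (with patient, coordinates, onset
#'   flag), `segments` (patient, segment_id, kind, start, end, onset_t) and
#'   `events` (patient, segment_id, channel, kind, peak_t; times absolute).
#' @export
simulate_preictal_cohort <- function(n_patients = 52, n_channels = 20,
                                     interictal_minutes = 10, preictal_s = 110,
                                     rates = list(ied_in = 1.13, ied_out = 0.76,
                                                  lows_in = 3.2, lows_out = 3.9),
                                     preictal_mult = list(ied_in = 1, ied_out = 1,
                                                          lows_in = 1.7, lows_out = 2.2),
                                     seed = 1L) {
  with_seed(seed, {
    chans <- list(); segs <- list(); evts <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      ct <- make_channel_table(n_channels, frac_resected = 0.2)
      ct$patient <- pid
      chans[[p]] <- ct
      # one interictal segment at t=0, one seizure file 3 h later
      onset_abs <- 3 * 3600 + preictal_s + 10
      seg <- data.frame(
        patient = pid, segment_id = c("interictal01", "sz01"),
        kind = c("interictal", "seizure"),
        start = c(0, 3 * 3600 + 10),
        end = c(interictal_minutes * 60, onset_abs + 60),
        onset_t = c(NA, onset_abs),
        onset_channel = c(NA, ct$name[ct$onset][1]))
      segs[[p]] <- seg
      for (ci in seq_len(nrow(ct))) {
        inside <- ct$soz[ci]
        r_ied <- if (inside) rates$ied_in else rates$ied_out
        r_lows <- if (inside) rates$lows_in else rates$lows_out
        m_ied <- if (inside) preictal_mult$ied_in else preictal_mult$ied_out
        m_lows <- if (inside) preictal_mult$lows_in else preictal_mult$lows_out
        add <- function(seg_row, rate_ied, rate_lows) {
          span <- segs[[p]]$end[seg_row] - segs[[p]]$start[seg_row]
          ti <- poisson_refractory(rate_ied / 60, span, refractory = 0) +
            segs[[p]]$start[seg_row]
          tl <- poisson_refractory(rate_lows / 60, span, refractory = 0) +
            segs[[p]]$start[seg_row]
          data.frame(patient = pid, segment_id = segs[[p]]$segment_id[seg_row],
                     channel = ct$name[ci],
                     kind = rep(c("IED", "LoWS"), c(length(ti), length(tl))),
                     peak_t = c(ti, tl))
        }
        evts[[length(evts) + 1]] <- add(1, r_ied, r_lows)
        evts[[length(evts) + 1]] <- add(2, r_ied * m_ied, r_lows * m_lows)
      }
    }
    list(channels = do.call(rbind, chans),
         segments = do.call(rbind, segs),
         events = do.call(rbind, evts))
  })
}
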