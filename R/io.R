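# Tab-separated metadata tables in the BIDS-iEEG dialect: channels.tsv
# (electrode geometry and flags), events.tsv (detected or ground-truth
# events), participants.tsv (outcomes).

read_tsv_checked <- function(path, required, what) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a channels.tsv table
#'
#' Columns: name, x, y, z (mm), gray, soz, resected (0/1). A missing column
#' is a schema error.
#' @param path file path.
#' @return validated channels data.frame.
#' @export
read_channels_tsv <- function(path) {
  validate_channels(read_tsv_checked(
    path, c("name", "x", "y", "z", "gray", "soz", "resected"), "channels"))
}

#' @rdname read_channels_tsv
#' @param channels channels data.frame.
#' @export
write_channels_tsv <- function(channels, path) {
  ch <- validate_channels(channels)
  for (cc in c("gray", "soz", "resected")) ch[[cc]] <- as.integer(ch[[cc]])
  write_tsv(ch[, c("name", "x", "y", "z", "gray", "soz", "resected")], path)
}

#' Read / write an events.tsv table
#'
#' Columns: onset (s), duration (s), channel, kind; detector outputs add
#' amplitude and burst_id, the ground-truth log adds downstate.
#' @param path file path.
#' @return events data.frame.
#' @export
read_events_tsv <- function(path) {
  read_tsv_checked(path, c("onset", "duration", "channel", "kind"), "events")
}

#' @rdname read_events_tsv
#' @param events event table with `peak_t` (mapped to onset) or `onset`.
#' @export
write_events_tsv <- function(events, path) {
  onset <- if ("onset" %in% names(events)) events$onset else events$peak_t
  dur <- if ("duration" %in% names(events)) events$duration else 0
  df <- data.frame(onset = onset, duration = dur,
                   channel = events$channel, kind = events$kind)
  for (extra in c("amplitude", "burst_id", "downstate")) {
    if (extra %in% names(events)) df[[extra]] <- events[[extra]]
  }
  write_tsv(df, path)
}

#' Read / write a participants.tsv table
#'
#' Columns: patient, engel, ilae, lesional, therapy.
#' @param path file path.
#' @return participants data.frame.
#' @export
read_participants_tsv <- function(path) {
  read_tsv_checked(path, c("patient", "engel", "ilae", "lesional", "therapy"),
                   "participants")
}

#' @rdname read_participants_tsv
#' @param participants participants data.frame (a `patients` table from
#'   [simulate_cohort()] works: `engel_class` is mapped to `engel`).
#' @export
write_participants_tsv <- function(participants, path) {
  p <- participants
  if (!"engel" %in% names(p) && "engel_class" %in% names(p)) {
    p$engel <- p$engel_class
  }
  write_tsv(p[, c("patient", "engel", "ilae", "lesional", "therapy")], path)
}

#' Read a recording with its channel metadata
#'
#' Reads an EDF signal file and the accompanying channels.tsv, checks that
#' the channel names agree, rejects unsupported sampling frequencies (256 Hz
#' recordings are refused; analyses need at least 500 Hz), and drops
#' channels not flagged as gray matter.
#'
#' @param signal_path EDF file.
#' @param channels_path channels.tsv file.
#' @param segment_kind segment label for the recording.
#' @return list of `recording` (gray-matter channels only, uV) and
#'   `channels` (matching rows).
#' @export
read_recording <- function(signal_path, channels_path,
                           segment_kind = "interictal") {
  if (!file.exists(signal_path)) stop("no such file: ", signal_path, call. = FALSE)
  channels <- read_channels_tsv(channels_path)
  rec <- read_edf(signal_path, segment_kind = segment_kind)
  if (!setequal(rec$channels, channels$name)) {
    stop("channel names in ", channels_path,
         " do not match the signal header", call. = FALSE)
  }
  channels <- channels[match(rec$channels, channels$name), ]
  keep <- channels$gray
  rec$samples <- rec$samples[keep, , drop = FALSE]
  rec$channels <- rec$channels[keep]
  list(recording = rec, channels = channels[keep, ])
}

#' Write a recording plus channel metadata
#'
#' @param rec a [new_recording()].
#' @param channels channels table.
#' @param dir output directory (created if absent).
#' @param stem file stem; writes `<stem>_ieeg.edf` and `<stem>_channels.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_recording <- function(rec, channels, dir, stem = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, paste0(stem, "_ieeg.edf"))
  cp <- file.path(dir, paste0(stem, "_channels.tsv"))
  write_edf(rec, sp)
  write_channels_tsv(channels, cp)
  invisible(c(signal = sp, channels = cp))
}

#' Default analysis parameters
#'
#' Every detection and analysis threshold in one (nested) list, overridable
#' from a YAML config file. Units are given per entry.
#'
#' @param path optional YAML file whose entries override the defaults.
#' @return nested named list of parameters.
#' @export
ws_params <- function(path = NULL) {
  p <- list(
    preprocess = list(line_hz = 60, notch_q = 30,
                      wake_win_s = 10, wake_ratio_threshold = 1),
    ied = list(env_factor = 3.5, raw_factor = 4, merge_gap_s = 0.04,
               hp_hz = 5, burst_gap_s = 0.2),
    lows = list(percentile = 0.9, min_dur = 0.25, max_dur = 1,
                ied_radius_s = 1, downstate_margin = 0.4),
    excitability = list(half_window_s = 3, readout_s = 0.05,
                        baseline = c(-3, -1), log_base = exp(1)),
    interplay = list(soz_radius_mm = 10, preictal_gap_s = 10,
                     interictal_clear_s = 7200),
    stats = list(rout_q = 0.01, good_engel_max = 2),
    classify = list(n_repeats = 1000, split_fraction = 0.7, n_perm = 1000)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (grp in names(user)) {
      for (key in names(user[[grp]])) p[[grp]][[key]] <- user[[grp]][[key]]
    }
  }
  p
}
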