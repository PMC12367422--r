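#' Configuration for the synthetic iEEG generator
#'
#' Defaults emulate the study conditions reported for awake intracranial
#' recordings: IEDs at ~0.7/min and downstate-associated LoWS at ~3.8/min per
#' channel, a 1/f background with a superimposed wake alpha rhythm, IED
#' transients carrying 20-80 Hz energy and slow half-waves (0.5-4 Hz) with
#' concurrent 45-130 Hz (high-gamma) suppression.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz (>= 500; lower rates are rejected throughout).
#' @param duration recording length in seconds.
#' @param background_slope exponent of the 1/f^slope background PSD.
#' @param alpha_power amplitude of the 8-12 Hz wake rhythm relative to the
#'   background delta-band (0.5-4 Hz) RMS; values > 1 make wake epochs
#'   separable by the alpha/delta ratio.
#' @param ied_rate IED injections per minute of wake, per channel.
#' @param lows_rate LoWS injections per minute of wake, per channel.
#' @param ied_amp_factor IED template scale: the template's 20-80 Hz Hilbert
#'   envelope peak equals this multiple of the channel's mean background
#'   20-80 Hz envelope.
#' @param lows_percentile_target unitless in (0,1); injected half-wave
#'   amplitudes are placed above this quantile of the channel's background
#'   candidate half-waves.
#' @param downstate_depth fractional suppression of 45-130 Hz background
#'   amplitude during an injected wave, in [0,1].
#' @param delay_law list describing the IED-to-next-LoWS waiting time used
#'   when coupling is enabled: `list(dist = "exponential", mean = <s>)` or
#'   `list(dist = "gamma", mean = <s>, shape = <k>)`. `mean = NULL` defaults
#'   to half the chance-level waiting time `60 / lows_rate / 2`.
#' @param seed integer seed; all generator randomness is routed through it.
#' @return a `ws_sim_config` list.
#' @export
sim_config <- function(n_channels = 10, fs = 512, duration = 600,
                       background_slope = 1, alpha_power = 1.3,
                       ied_rate = 0.71, lows_rate = 3.82,
                       ied_amp_factor = 5, lows_percentile_target = 0.9,
                       downstate_depth = 0.8,
                       delay_law = list(dist = "exponential", mean = NULL),
                       seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid config: duration must be positive", call. = FALSE)
  }
  if (!is.numeric(fs) || fs < 500) {
    stop("invalid config: fs must be >= 500 Hz", call. = FALSE)
  }
  if (ied_rate < 0 || lows_rate < 0) {
    stop("invalid config: rates must be >= 0", call. = FALSE)
  }
  if (downstate_depth < 0 || downstate_depth > 1) {
    stop("invalid config: downstate_depth must lie in [0, 1]", call. = FALSE)
  }
  if (lows_percentile_target <= 0 || lows_percentile_target >= 1) {
    stop("invalid config: lows_percentile_target must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    background_slope = background_slope, alpha_power = alpha_power,
    ied_rate = ied_rate, lows_rate = lows_rate,
    ied_amp_factor = ied_amp_factor,
    lows_percentile_target = lows_percentile_target,
    downstate_depth = downstate_depth, delay_law = delay_law,
    seed = as.integer(seed)
  ), class = "ws_sim_config")
}

# one channel of Gaussian 1/f^slope noise, unit RMS, via spectral shaping;
# band-limited at 130 Hz as in clinical acquisition chains (also the top of
# the high-gamma analysis band)
pink_noise <- function(n, fs, slope, f_hi = 130) {
  m <- stats::nextn(n, c(2, 3, 5))
  freqs <- c(0, seq_len(m - 1)) * fs / m
  half <- freqs[2:(floor(m / 2) + 1)]
  amp <- half^(-slope / 2)
  # roll off below 0.1 Hz so DC does not dominate
  amp[half < 0.1] <- (0.1)^(-slope / 2)
  amp <- amp / sqrt(1 + (half / f_hi)^8)    # soft acquisition low-pass
  phases <- stats::runif(length(half), 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(m))
  full[2:(floor(m / 2) + 1)] <- spec
  if (m %% 2 == 0) {
    full[m / 2 + 1] <- complex(real = Mod(spec[length(spec)]))
    full[seq(m, m / 2 + 2)] <- Conj(full[2:(m / 2)])
  } else {
    full[seq(m, (m + 3) / 2)] <- Conj(full[2:((m + 1) / 2)])
  }
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

#' Generate a synthetic background recording
#'
#' Per-channel Gaussian noise with power spectral density proportional to
#' `1/f^background_slope`, plus an 8-12 Hz alpha rhythm during simulated wake
#' blocks. Wake and (alpha-free) rest alternate in 30-s blocks, starting with
#' wake, so the alpha/delta wake criterion has something to reject. The true
#' block schedule is stored in the `wake_truth` attribute.
#'
#' @param config a [sim_config()].
#' @return a [new_recording()] with attribute `wake_truth` (logical per
#'   sample) and `bg_rms` (background RMS in uV).
#' @export
make_background <- function(config) {
  stopifnot(inherits(config, "ws_sim_config"))
  with_seed(config$seed, {
    n <- round(config$duration * config$fs)
    bg_rms <- 25  # microvolts, typical awake iEEG background
    block <- 30   # seconds per wake/rest block
    tt <- (seq_len(n) - 1) / config$fs
    wake_truth <- (floor(tt / block) %% 2) == 0
    samples <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      x <- pink_noise(n, config$fs, config$background_slope) * bg_rms
      if (config$alpha_power > 0) {
        delta_rms <- sqrt(mean(filt_bandpass(x, config$fs, 0.5, 4)^2))
        a <- filt_bandpass(stats::rnorm(n), config$fs, 8, 12)
        a <- a / stats::sd(a) * config$alpha_power * delta_rms
        x <- x + a * wake_truth
      }
      samples[ch, ] <- x
    }
    rec <- new_recording(samples, fs = config$fs)
    attr(rec, "wake_truth") <- wake_truth
    attr(rec, "bg_rms") <- bg_rms
    rec
  })
}

# IED template: sharp Mexican-hat spike (sigma 8 ms, spectral peak ~28 Hz)
# riding on an aligned slower wave (sigma 18 ms), as in clinical spike-wave
# transients whose raw peak exceeds their 20-80 Hz envelope; ~150 ms support,
# unit peak
ied_template <- function(fs, sigma = 0.008, hump_sigma = 0.018, hump_amp = 2.8) {
  t <- seq(-0.075, 0.075, by = 1 / fs)
  spike <- (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
  w <- spike / max(abs(spike)) + hump_amp * exp(-t^2 / (2 * hump_sigma^2))
  w / max(abs(w))
}

# raised-cosine half-wave of duration D seconds, unit peak, one polarity lobe
lows_template <- function(fs, duration) {
  t <- seq(0, duration, by = 1 / fs)
  sin(pi * t / duration)
}

# homogeneous Poisson times on [0, span) with a hard refractory spacing,
# returned sorted; rate in events per second
poisson_refractory <- function(rate, span, refractory = 0.5) {
  if (rate <= 0 || span <= refractory) return(numeric(0))
  # exponential gaps plus dead time; effective rate matches `rate`
  eff <- rate / (1 - rate * refractory)
  if (eff <= 0) stop("scheduling error: rate infeasible at 0.5 s spacing", call. = FALSE)
  times <- numeric(0)
  t <- stats::rexp(1, eff)
  while (t < span) {
    times <- c(times, t)
    t <- t + refractory + stats::rexp(1, eff)
  }
  times
}

# draw one waiting time from a delay law
draw_delay <- function(law, n = 1, mean_default) {
  m <- if (is.null(law$mean)) mean_default else law$mean
  if (identical(law$dist, "gamma")) {
    k <- if (is.null(law$shape)) 2 else law$shape
    stats::rgamma(n, shape = k, rate = k / m)
  } else {
    stats::rexp(n, rate = 1 / m)
  }
}

# amplitudes of background candidate half-waves (duration in [0.25, 1] s)
background_halfwave_amps <- function(x, fs) {
  lf <- filt_bandpass(x, fs, 0.5, 4)
  zc <- zero_crossings(lf)
  if (length(zc) < 2) return(numeric(0))
  dur <- diff(zc) / fs
  ok <- which(dur >= 0.25 & dur <= 1)
  vapply(ok, function(i) max(abs(lf[(zc[i] + 1):zc[i + 1]])), numeric(1))
}

#' Inject IED and LoWS events into a background recording
#'
#' IEDs are sharp biphasic transients whose 20-80 Hz Hilbert-envelope peak is
#' `ied_amp_factor` times the channel's mean background 20-80 Hz envelope.
#' LoWS are raised-cosine half-waves with durations drawn from [0.25, 1] s,
#' scaled above the channel's `lows_percentile_target` quantile of background
#' candidate half-wave amplitudes; waves flagged as downstates have the
#' background 45-130 Hz content multiplicatively suppressed by
#' `downstate_depth` for the wave's duration. Events are scheduled as
#' homogeneous Poisson processes (0.5-s refractory spacing) inside wake
#' blocks only, away from block edges, so rates are per minute of wake.
#'
#' @param rec background from [make_background()] (or any `ws_recording` with
#'   a `wake_truth` attribute; without one the whole recording counts as wake).
#' @param config a [sim_config()].
#' @param ied_times,lows_times optional lists (one numeric vector per channel)
#'   of explicit injection times in seconds, overriding Poisson scheduling.
#' @param lows_downstate optional list of logical vectors parallel to
#'   `lows_times`; default all `TRUE` (every injected wave has a downstate).
#' @param downstate_prob probability an injected wave carries a downstate when
#'   scheduling is random (default 1).
#' @return list with elements `recording` (events added) and `truth`
#'   (data.frame: kind, channel, peak_t, amplitude, duration, downstate),
#'   sorted by channel then time.
#' @export
inject_events <- function(rec, config, ied_times = NULL, lows_times = NULL,
                          lows_downstate = NULL, downstate_prob = 1) {
  stopifnot(inherits(rec, "ws_recording"), inherits(config, "ws_sim_config"))
  if (rec_duration(rec) <= 10) stop("recording must be longer than 10 s", call. = FALSE)
  fs <- rec$fs
  n <- ncol(rec$samples)
  wake_truth <- attr(rec, "wake_truth")
  if (is.null(wake_truth)) wake_truth <- rep(TRUE, n)

  # wake blocks shrunk by a margin so event support and downstate flanks stay
  # inside a single wake block and away from recording edges
  margin <- 2.0
  r <- rle(wake_truth)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  blocks <- cbind(start = (starts[r$values] - 1) / fs + margin,
                  end   = ends[r$values] / fs - margin)
  blocks <- blocks[blocks[, "end"] - blocks[, "start"] > 1, , drop = FALSE]
  blocks[, "start"] <- pmax(blocks[, "start"], 4)
  blocks[, "end"] <- pmin(blocks[, "end"], rec_duration(rec) - 4)
  blocks <- blocks[blocks[, "end"] > blocks[, "start"], , drop = FALSE]
  spans <- blocks[, "end"] - blocks[, "start"]
  total_span <- sum(spans)

  # map a time on the concatenated wake axis back to recording time
  unfold <- function(u) {
    cum <- c(0, cumsum(spans))
    k <- findInterval(u, cum, rightmost.closed = TRUE)
    k <- pmin(k, nrow(blocks))
    blocks[k, "start"] + (u - cum[k])
  }

  with_seed(config$seed + 1L, {
    truth <- list()
    for (ch in seq_len(config$n_channels)) {
      x <- rec$samples[ch, ]

      # channel reference levels from the pre-injection background
      env2080 <- hilbert_envelope(filt_bandpass(x, fs, 20, 80))
      m2080 <- mean(env2080)
      bg_amps <- background_halfwave_amps(x, fs)
      q_target <- if (length(bg_amps)) {
        stats::quantile(bg_amps, config$lows_percentile_target, names = FALSE)
      } else stats::sd(x)

      # --- schedule ---
      if (is.null(ied_times)) {
        it <- sort(unfold(poisson_refractory(config$ied_rate / 60, total_span)))
      } else it <- sort(ied_times[[ch]])
      if (is.null(lows_times)) {
        # 2-s spacing keeps injected waves (and their delta-band footprint)
        # from piling up within one wake-scoring window
        lt <- sort(unfold(poisson_refractory(config$lows_rate / 60, total_span,
                                             refractory = 2)))
        # keep waves clear of IEDs so the 1-s exclusion rule does not censor
        # injected ground truth
        if (length(it) && length(lt)) {
          near <- vapply(lt, function(t) any(abs(t - it) < 1.3), logical(1))
          lt <- lt[!near]
        }
        ds <- stats::runif(length(lt)) < downstate_prob
      } else {
        lt <- lows_times[[ch]]
        ds <- if (is.null(lows_downstate)) rep(TRUE, length(lt)) else lows_downstate[[ch]]
        ds <- ds[order(lt)]
        lt <- sort(lt)
      }

      # --- inject IEDs ---
      if (length(it)) {
        tmpl <- ied_template(fs)
        tenv <- hilbert_envelope(filt_bandpass(
          c(numeric(fs), tmpl, numeric(fs)), fs, 20, 80))
        resp <- max(tenv)  # band-envelope peak of the unit template
        scale <- config$ied_amp_factor * m2080 / resp
        half <- (length(tmpl) - 1) / 2
        for (t in it) {
          i0 <- time_to_index(rec, t) - half
          idx <- i0:(i0 + length(tmpl) - 1)
          ok <- idx >= 1 & idx <= n
          x[idx[ok]] <- x[idx[ok]] + scale * tmpl[ok]
          truth[[length(truth) + 1]] <- data.frame(
            kind = "IED", channel = rec$channels[ch], peak_t = t,
            amplitude = scale, duration = length(tmpl) / fs, downstate = FALSE)
        }
      }

      # --- inject LoWS ---
      if (length(lt)) {
        hg <- filt_bandpass(x, fs, 45, min(130, fs / 2 - 5))
        for (k in seq_along(lt)) {
          t <- lt[k]
          D <- stats::runif(1, 0.3, 0.8)
          # compensate the 0.5-4 Hz filter response so the *filtered*
          # half-wave amplitude (what the detector measures) lands at the
          # target headroom above the channel's percentile, regardless of D
          resp_D <- max(abs(filt_bandpass(
            c(numeric(fs), lows_template(fs, D), numeric(fs)), fs, 0.5, 4)))
          amp <- q_target * stats::runif(1, 1.9, 2.4) / resp_D
          pol <- sample(c(-1, 1), 1)
          tmpl <- lows_template(fs, D) * amp * pol
          i0 <- time_to_index(rec, t - D / 2)
          idx <- i0:(i0 + length(tmpl) - 1)
          ok <- idx >= 1 & idx <= n
          x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
          if (ds[k] && config$downstate_depth > 0) {
            # multiplicative HG suppression with cosine ramps at the edges
            ramp <- lows_template(fs, D)  # reuse the half-sine as a taper
            x[idx[ok]] <- x[idx[ok]] -
              config$downstate_depth * ramp[ok] * hg[idx[ok]]
          }
          truth[[length(truth) + 1]] <- data.frame(
            kind = "LoWS", channel = rec$channels[ch], peak_t = t,
            amplitude = amp, duration = D, downstate = isTRUE(ds[k]))
        }
      }
      rec$samples[ch, ] <- x
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(kind = character(0), channel = character(0),
                 peak_t = numeric(0), amplitude = numeric(0),
                 duration = numeric(0), downstate = logical(0))
    truth <- truth[order(truth$channel, truth$peak_t), , drop = FALSE]
    rownames(truth) <- NULL
    stopifnot(all(truth$peak_t > 0), all(truth$peak_t < rec_duration(rec)))
    list(recording = rec, truth = truth)
  })
}
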