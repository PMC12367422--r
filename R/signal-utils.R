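# Internal DSP helpers. All filters are zero-phase (forward-backward) IIR so
# that event peak latencies -- on which every delay statistic depends -- are
# preserved.

#' Run code with a temporarily seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Analytic-signal amplitude envelope via the frequency-domain Hilbert method.
#' @noRd
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / m
  Mod(z[seq_len(n)])
}

#' Zero-phase Butterworth band-pass.
#' @noRd
filt_bandpass <- function(x, fs, lo, hi, order = 4) {
  ny <- fs / 2
  stopifnot(lo > 0, hi < ny, lo < hi)
  bf <- signal::butter(order / 2, c(lo, hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase Butterworth high-pass.
#' @noRd
filt_highpass <- function(x, fs, lo, order = 4) {
  ny <- fs / 2
  stopifnot(lo > 0, lo < ny)
  bf <- signal::butter(order, lo / ny, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Mean band power (uV^2) of a segment via zero-phase band-pass.
#' @noRd
bandpower <- function(x, fs, lo, hi) {
  mean(filt_bandpass(x, fs, lo, hi)^2)
}

#' Sliding-window Hanning-taper power spectrogram.
#'
#' Windows of `win_s` seconds stepped by `step_s`; power returned for
#' frequency bins within [fmin, fmax]. Times are window centres in seconds
#' relative to the start of `x`.
#' @noRd
stft_power <- function(x, fs, win_s = 0.2, step_s = NULL, fmin = 45, fmax = 130) {
  if (is.null(step_s)) step_s <- win_s / 10  # 90% overlap
  nwin <- round(win_s * fs)
  nstep <- max(1L, round(step_s * fs))
  n <- length(x)
  stopifnot(n >= nwin)
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann taper
  freqs <- (seq_len(nwin) - 1L) * fs / nwin
  keep <- which(freqs >= fmin & freqs <= fmax)
  pw <- vapply(starts, function(s) {
    seg <- x[s:(s + nwin - 1L)] * w
    (Mod(stats::fft(seg))^2)[keep] / sum(w^2) / fs
  }, numeric(length(keep)))
  if (is.null(dim(pw))) pw <- matrix(pw, nrow = length(keep))
  list(
    power = pw,                                  # freq x time
    freqs = freqs[keep],
    times = (starts - 1L + (nwin - 1L) / 2) / fs
  )
}

#' Indices of sign changes (zero-crossings) of a numeric vector.
#' Returns the index i such that x[i] and x[i+1] have opposite (strict) signs;
#' zeros are absorbed into the preceding sign run.
#' @noRd
zero_crossings <- function(x) {
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  cs <- cumsum(nz)
  cs[cs == 0L] <- 1L           # leading zeros take the first non-zero sign
  s_filled <- s[nz][cs]
  which(diff(s_filled) != 0)
}
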