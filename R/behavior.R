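## Behavioral metrics: kinematic onset/offset detection, reaction time,
## movement duration, and in-movement / pre-movement RMS EMG.

#' Detect movement onsets and offsets from a kinematic trace
#'
#' For each cue, the trial window (cue to next cue, or trace end) is
#' scanned; the onset is the first sample exceeding `thresholdFraction` of
#' the trial peak, the offset the last sample above that threshold. Trials
#' whose peak does not rise above `minAmplitude` never cross the threshold
#' and are dropped with a warning.
#'
#' @param kin Numeric kinematic trace (flexion positive).
#' @param cues Integer cue sample indices, one per trial.
#' @param srate Kinematic sampling rate.
#' @param thresholdFraction Fraction of the trial peak (default 0.1).
#' @param minAmplitude Minimum trial peak for a movement to count.
#' @param minDurationS Shortest excursion accepted as movement (s); brief
#'   noise spikes above threshold are ignored (default 0.1 s).
#' @param smoothS Moving-average window applied before thresholding (s);
#'   suppresses sensor noise without shifting the edge (default 0.05 s).
#' @return A `movementEvents` data.frame (trial, cue, onset, offset) with a
#'   `srate` attribute; dropped trials are omitted.
#' @export
detectOnsets <- function(kin, cues, srate, thresholdFraction = 0.1,
                         minAmplitude = 0.1, minDurationS = 0.1,
                         smoothS = 0.05) {
  if (any(!is.finite(kin))) stop("kinematic trace must be finite")
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must be in (0, 1)")
  w <- max(1L, round(smoothS * srate))
  if (w > 1L) {
    pad <- c(rep(kin[1], w), kin, rep(kin[length(kin)], w))
    sm <- stats::filter(pad, rep(1 / w, w), sides = 2)
    kin <- as.numeric(sm[(w + 1):(w + length(kin))])
  }
  minRun <- max(2L, round(minDurationS * srate))
  rows <- list()
  for (tr in seq_along(cues)) {
    a <- cues[tr]
    b <- if (tr < length(cues)) cues[tr + 1] - 1L else length(kin)
    seg <- kin[a:b]
    peak <- max(seg)
    runs <- rle(seg >= thresholdFraction * peak)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sustained <- which(runs$values & runs$lengths >= minRun)
    if (peak < minAmplitude || !length(sustained)) {
      warning(sprintf("trial %d never crosses threshold; dropped", tr))
      next
    }
    onset <- a + starts[sustained[1]] - 1L
    offset <- a + ends[sustained[length(sustained)]] - 1L
    rows[[length(rows) + 1L]] <-
      data.frame(trial = tr, cue = a, onset = onset, offset = offset)
  }
  if (!length(rows)) {
    out <- data.frame(trial = integer(0), cue = integer(0),
                      onset = integer(0), offset = integer(0))
  } else out <- do.call(rbind, rows)
  attr(out, "srate") <- srate
  class(out) <- c("movementEvents", "data.frame")
  out
}

#' Reaction time from movement events
#'
#' `(onset - cue) / srate * 1000`, in milliseconds, one value per retained
#' trial.
#'
#' @param events A `movementEvents` object from [detectOnsets()].
#' @return Numeric vector (ms).
#' @export
reactionTime <- function(events) {
  srate <- attr(events, "srate")
  if (any(events$onset < events$cue)) stop("onset precedes cue")
  (events$onset - events$cue) / srate * 1000
}

#' Movement duration from movement events
#'
#' `(offset - onset) / srate * 1000`, in milliseconds.
#'
#' @param events A `movementEvents` object.
#' @return Numeric vector (ms).
#' @export
movementDuration <- function(events) {
  srate <- attr(events, "srate")
  (events$offset - events$onset) / srate * 1000
}

#' RMS EMG per trial, in-movement or pre-movement
#'
#' The EMG trace is band-pass filtered (20-450 Hz, 4th-order zero-phase
#' Butterworth), then squared, averaged and square-rooted over either the
#' movement window `[onset, offset]` or the `preMs` milliseconds preceding
#' the onset. Event indices are rescaled from the kinematic to the EMG
#' sampling rate. Windows shorter than 3 filter orders are dropped with a
#' warning.
#'
#' @param emg Numeric EMG trace.
#' @param srate EMG sampling rate (> 900 required when filtering).
#' @param events `movementEvents` (indices at `attr(events, "srate")`).
#' @param band Passband (Hz); `NULL` skips filtering.
#' @param window `"movement"` or `"premovement"`.
#' @param preMs Pre-movement window length (ms, default 500).
#' @param order Filter order.
#' @return Numeric vector of per-trial RMS values (microvolts); the
#'   per-condition summary is their mean.
#' @export
rmsEmg <- function(emg, srate, events, band = c(20, 450),
                   window = c("movement", "premovement"), preMs = 500,
                   order = 4) {
  window <- match.arg(window)
  if (!is.null(band)) {
    if (srate <= 2 * band[2]) stop("EMG sampling rate too low for the band")
    if (srate <= 900) stop("EMG sampling rate must exceed 900 samples/s")
    bf <- signal::butter(order, band / (srate / 2), type = "pass")
    emg <- signal::filtfilt(bf, emg)
  }
  evSr <- attr(events, "srate")
  sc <- srate / evSr
  out <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    on <- round((events$onset[i] - 1) * sc) + 1L
    off <- round((events$offset[i] - 1) * sc) + 1L
    idx <- if (window == "movement") on:off else {
      w <- round(preMs * srate / 1000)
      max(1L, on - w):(on - 1L)
    }
    idx <- idx[idx >= 1L & idx <= length(emg)]
    if (length(idx) <= 3 * order) {
      warning(sprintf("trial %d window too short; dropped", events$trial[i]))
      next
    }
    out[i] <- sqrt(mean(emg[idx]^2))
  }
  out
}
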