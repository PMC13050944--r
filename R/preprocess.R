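## Preprocessing chain: band-pass filtering, downsampling, bad-channel
## interpolation, common average reference, baseline correction and
## onset-locked pre-movement epoch extraction.

.asChannelMatrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-backward (zero phase; the effective magnitude order doubles).
#' Output length equals input length.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param lowHz,highHz Passband edges (Hz), `0 < lowHz < highHz < srate/2`.
#' @param srate Sampling rate (samples/s).
#' @param order Filter order (default 4).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, lowHz = 0.5, highHz = 30, srate, order = 4) {
  if (lowHz <= 0 || highHz <= lowHz || highHz >= srate / 2)
    stop("passband must satisfy 0 < lowHz < highHz < srate/2")
  if (order < 1) stop("order must be >= 1")
  vec <- is.null(dim(x))
  x <- .asChannelMatrix(x)
  if (ncol(x) <= 3 * order)
    stop("series too short for the requested filter order")
  bf <- signal::butter(order, c(lowHz, highHz) / (srate / 2), type = "pass")
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  if (vec) drop(out) else out
}

#' Band-stop filter at the mains frequency
#'
#' Applied before the band-pass; with a 0.5-30 Hz passband the notch is a
#' practical no-op but keeps the stage explicit for wider-band use.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param srate Sampling rate.
#' @param mainsHz Mains frequency (default 50).
#' @param widthHz Half-width of the stop band (default 2).
#' @param order Filter order (default 2).
#' @return Filtered data, same shape as `x`.
#' @export
lineNoiseFilter <- function(x, srate, mainsHz = 50, widthHz = 2, order = 2) {
  if (mainsHz + widthHz >= srate / 2)
    stop("stop band exceeds Nyquist")
  vec <- is.null(dim(x))
  x <- .asChannelMatrix(x)
  bf <- signal::butter(order, c(mainsHz - widthHz, mainsHz + widthHz) / (srate / 2),
                       type = "stop")
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  if (vec) drop(out) else out
}

#' Anti-aliased integer-ratio downsampling
#'
#' Applies a zero-phase Butterworth low-pass at 80% of the target Nyquist,
#' then keeps every q-th sample (q = srateIn / srateOut, which must be an
#' integer). The output has `floor(n * srateOut / srateIn)` samples.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param srateIn,srateOut Input and output sampling rates.
#' @return Decimated data.
#' @export
downsample <- function(x, srateIn, srateOut) {
  q <- srateIn / srateOut
  if (abs(q - round(q)) > 1e-9)
    stop("srateIn must be an integer multiple of srateOut")
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  vec <- is.null(dim(x))
  x <- .asChannelMatrix(x)
  bf <- signal::butter(4, 0.8 / q, type = "low")
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  keep <- seq(1L, by = q, length.out = floor(ncol(x) / q))
  out <- out[, keep, drop = FALSE]
  if (vec) drop(out) else out
}

#' Flag channels with outlying variance
#'
#' A lightweight stand-in bad-channel detector: channels whose log-variance
#' z-score exceeds the threshold are flagged. The z-score uses the robust
#' median/MAD scale so that a single extreme channel cannot mask itself by
#' inflating the spread estimate.
#'
#' @param x channels x samples matrix.
#' @param zThreshold Absolute z-score threshold (default 5).
#' @return Integer vector of flagged channel indices (possibly empty).
#' @export
flagBadChannels <- function(x, zThreshold = 5) {
  v <- log(apply(x, 1, var) + 1e-300)
  z <- (v - stats::median(v)) / max(stats::mad(v), 1e-12)
  which(abs(z) > zThreshold)
}

#' Interpolate bad channels from montage neighbors
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of its
#' nearest good neighbors (3 by default, from the idealized montage).
#'
#' @param x channels x samples matrix (rows ordered as `nbhd$labels`).
#' @param bad Integer indices or channel labels of bad channels.
#' @param nbhd A `channelNeighborhood` from [channelNeighbors()].
#' @return `x` with bad rows replaced.
#' @export
interpolateBadChannels <- function(x, bad, nbhd) {
  stopifnot(inherits(nbhd, "channelNeighborhood"))
  if (is.character(bad)) bad <- match(bad, nbhd$labels)
  bad <- as.integer(bad)
  if (any(is.na(bad))) stop("unknown bad channel")
  if (length(bad) >= nrow(x)) stop("bad channels must be a strict subset")
  out <- x
  for (b in bad) {
    nb <- nbhd$neighbors[b, ]
    d <- nbhd$distances[b, ]
    good <- !(nb %in% bad)
    if (!any(good))
      stop(sprintf("all neighbors of channel %d are bad", b))
    w <- 1 / d[good]
    w <- w / sum(w)
    out[b, ] <- drop(w %*% x[nb[good], , drop = FALSE])
  }
  out
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels at every sample, so the
#' channel mean is exactly zero afterwards. Idempotent.
#'
#' @param x channels x samples matrix (>= 2 channels).
#' @return Re-referenced matrix.
#' @export
rereferenceAverage <- function(x) {
  x <- .asChannelMatrix(x)
  if (nrow(x) < 2L) stop("average reference needs >= 2 channels")
  x - rep(colMeans(x), each = nrow(x))
}

#' Extract baseline-corrected pre-movement epochs
#'
#' Cuts one epoch per movement onset out of a continuous recording. The
#' window is half-open: `[onset + start_ms, onset + end_ms)`, so with the
#' default (-500, 0) ms window the onset sample itself is excluded. Each
#' epoch is baseline-corrected by subtracting the channel's whole-epoch
#' mean. Onsets with insufficient preceding data are dropped with a warning.
#'
#' @param x channels x samples continuous matrix.
#' @param onsets Integer onset sample indices.
#' @param windowMs (start_ms, end_ms) relative to onset, end <= 0.
#' @param srate Sampling rate.
#' @return List: `epochs` (trials x channels x samples array), `kept`
#'   (indices of retained onsets), `dropped`.
#' @export
extractPremovementEpochs <- function(x, onsets, windowMs = c(-500, 0), srate) {
  x <- .asChannelMatrix(x)
  if (windowMs[2] > 0) stop("pre-movement window must end at or before 0 ms")
  nWin <- round((windowMs[2] - windowMs[1]) * srate / 1000)
  if (nWin < 1) stop("empty window")
  startOff <- round(windowMs[1] * srate / 1000)
  keep <- integer(0); epochs <- list()
  for (i in seq_along(onsets)) {
    s0 <- onsets[i] + startOff
    s1 <- s0 + nWin - 1L
    if (s0 < 1L || s1 > ncol(x)) next
    ep <- x[, s0:s1, drop = FALSE]
    ep <- ep - rowMeans(ep)                  # baseline correction
    keep <- c(keep, i)
    epochs[[length(epochs) + 1L]] <- ep
  }
  dropped <- setdiff(seq_along(onsets), keep)
  if (length(dropped))
    warning(sprintf("dropped %d onset(s) too close to the recording edge: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!length(epochs)) stop("no epoch could be extracted")
  arr <- array(0, dim = c(length(epochs), nrow(x), nWin))
  for (i in seq_along(epochs)) arr[i, , ] <- epochs[[i]]
  list(epochs = arr, kept = keep, dropped = dropped)
}
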