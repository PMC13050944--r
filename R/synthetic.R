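## Synthetic multi-subject epoched EEG with planted microstate structure,
## plus behavioral, kinematic and EMG series. The generator is the ground
## truth against which every downstream stage is validated.

#' Ground truth for the synthetic generator
#'
#' Bundles the planted template maps, their per-condition prevalences, the
#' dwell model, the signal-to-noise ratio, and the behavioral/EMG effect
#' sizes. All invariants (centered unit-norm maps, prevalences summing to
#' one, positive dwell and SNR) are enforced at construction.
#'
#' @param plantedMaps K x channels matrix of template topographies; centered
#'   and L2-normalized on construction.
#' @param prevalence conditions x K matrix (recycled over subjects) or
#'   subjects x conditions x K array of expected per-map fractions of
#'   timepoints; every (subject, condition) row must sum to 1.
#' @param segmentDwell Mean dwell length per planted segment, samples (>= 1).
#' @param snr Ratio of template-signal RMS to additive-noise RMS (> 0).
#' @param emgScale Per-condition EMG amplitude multiplier.
#' @param rtShift Per-condition reaction-time offset (ms).
#' @param mapJitter SD of the per-segment topographic jitter applied to the
#'   planted map before normalization (0 = identical map every visit).
#' @param templateAmplitudeUv Nominal peak amplitude of a planted segment
#'   (microvolts).
#' @param seed Integer RNG seed; all generator randomness derives from it.
#' @return A list of class `groundTruth`.
#' @export
groundTruth <- function(plantedMaps, prevalence, segmentDwell = 12,
                        snr = 2, emgScale = NULL, rtShift = NULL,
                        mapJitter = 0.05, templateAmplitudeUv = 5,
                        seed = 1L) {
  plantedMaps <- normalizeMaps(as.matrix(plantedMaps))
  K <- nrow(plantedMaps)
  if (is.matrix(prevalence)) {
    if (ncol(prevalence) != K) stop("prevalence columns must match map count")
    prevalence <- array(rep(prevalence, each = 1),
                        dim = c(1, nrow(prevalence), K))
  }
  if (length(dim(prevalence)) != 3L || dim(prevalence)[3] != K)
    stop("prevalence must be conditions x K or subjects x conditions x K")
  sums <- apply(prevalence, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("prevalences over maps must sum to 1 for every subject x condition")
  if (any(prevalence < 0)) stop("prevalences must be non-negative")
  if (segmentDwell < 1) stop("segmentDwell must be >= 1 sample")
  if (snr <= 0) stop("snr must be > 0")
  nCond <- dim(prevalence)[2]
  if (is.null(emgScale)) emgScale <- seq(0.3, 2.2, length.out = nCond)
  if (is.null(rtShift)) rtShift <- c(0, seq(0, 50, length.out = nCond - 1))[seq_len(nCond)]
  if (length(emgScale) != nCond || length(rtShift) != nCond)
    stop("emgScale and rtShift must have one entry per condition")
  if (any(emgScale <= 0)) stop("emgScale must be positive")
  structure(list(plantedMaps = plantedMaps, prevalence = prevalence,
                 segmentDwell = segmentDwell, snr = snr,
                 emgScale = emgScale, rtShift = rtShift,
                 mapJitter = mapJitter,
                 templateAmplitudeUv = templateAmplitudeUv,
                 seed = as.integer(seed)),
            class = "groundTruth")
}

#' Study-like default ground truth
#'
#' Eight smooth, mutually orthogonalized planted maps on the 32-channel
#' montage; five conditions (one unloaded baseline plus four graded loads);
#' the prevalence of map 2 declines monotonically across the four load
#' conditions (the planted load effect) while the other maps share the
#' remainder equally; SNR 2, mean dwell 12 samples (48 ms at 250 Hz).
#'
#' @param K Number of planted maps (default 8).
#' @param nConditions Number of conditions (default 5).
#' @param nChannels Channel count (default 32, the standard montage).
#' @param effectMap Which map carries the declining-prevalence load effect.
#' @param prevalenceRange Prevalence of the effect map in the first and last
#'   load condition (linear in between; the baseline condition uses the
#'   first value).
#' @param seed Integer seed (drives map generation and all downstream
#'   randomness).
#' @param ... Further arguments passed to [groundTruth()].
#' @return A `groundTruth` object.
#' @export
defaultGroundTruth <- function(K = 8, nConditions = 5, nChannels = 32,
                               effectMap = 2, prevalenceRange = c(0.25, 0.05),
                               seed = 1L, ...) {
  plantedMaps <- .smoothOrthogonalMaps(K, nChannels, seed = seed)
  # baseline condition at the high-prevalence end, then a linear decline
  pEff <- c(prevalenceRange[1],
            seq(prevalenceRange[1], prevalenceRange[2],
                length.out = nConditions - 1))[seq_len(nConditions)]
  prevalence <- matrix(0, nConditions, K)
  for (c in seq_len(nConditions)) {
    prevalence[c, ] <- (1 - pEff[c]) / (K - 1)
    prevalence[c, effectMap] <- pEff[c]
  }
  groundTruth(plantedMaps, prevalence, seed = seed, ...)
}

## K smooth orthogonal topographies: random dipolar/quadrupolar patterns on
## the montage sphere, centered, then orthogonalized by QR within the
## average-reference subspace
.smoothOrthogonalMaps <- function(K, nChannels, seed) {
  pos <- if (nChannels == 32) montagePositions() else {
    # generic spiral montage for non-standard channel counts
    i <- seq_len(nChannels)
    z <- 1 - (i - 0.5) * (2 / nChannels) * 0.9
    th <- pi * (3 - sqrt(5)) * i
    cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  }
  set.seed(.subSeed(seed, 101L))
  raw <- matrix(0, K, nChannels)
  for (k in seq_len(K)) {
    d1 <- rnorm(3); d2 <- rnorm(3)
    raw[k, ] <- pos %*% d1 + (pos %*% d2)^2 * sign(rnorm(1))
  }
  raw <- raw - rowMeans(raw)
  qr_ <- qr(t(raw))
  ortho <- t(qr.Q(qr_)[, seq_len(K), drop = FALSE])
  normalizeMaps(ortho - rowMeans(ortho))
}

## spatially correlated pink noise: per-channel 1/f spectra mixed through a
## montage-distance smoothing kernel
.pinkNoise <- function(nChannels, nSamples, srate, mixChol) {
  W <- matrix(rnorm(nSamples * nChannels), nSamples, nChannels)
  f <- c(0, seq_len(nSamples - 1)) * srate / nSamples
  f <- pmin(f, srate - f)                     # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, 0.5))               # 1/f power below ~Nyquist
  shaped <- Re(stats::mvfft(stats::mvfft(W) * amp, inverse = TRUE)) / nSamples
  crossprod(mixChol, t(shaped))               # channels x samples, cov ~ C
}

.noiseMixChol <- function(pos, lambda = 1.0) {
  u <- pos / sqrt(rowSums(pos^2))
  cosang <- tcrossprod(u); cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  d <- acos(cosang)
  C <- exp(-(d / lambda)^2)
  chol(C + diag(1e-6, nrow(C)))
}

#' Generate epoched EEG with planted microstate structure
#'
#' Every epoch is a concatenation of dwell segments. Within a segment the
#' signal is `plantedMap[k] * envelope * sign`, where the envelope is a
#' smooth positive arch (one GFP maximum per segment), the polarity sign is
#' random per segment, and `k` is drawn from the subject x condition
#' prevalence. Spatially correlated 1/f noise is added at the requested SNR,
#' and the result is average-referenced. The realized per-sample segment
#' labels are returned as ground truth in the `truth` slot.
#'
#' @param truth A `groundTruth` object.
#' @param nSubjects,nConditions,nTrials Design counts (>= 1).
#' @param nSamples Samples per epoch (default 125 = 500 ms at 250 Hz).
#' @param srate Sampling rate (default 250).
#' @return An [EpochSet-class]; `@truth` holds `plantedMaps`, `prevalence`,
#'   `labels` (subject x condition x trial x sample planted map index) and
#'   `seed`.
#' @export
generateEpochs <- function(truth, nSubjects = 10, nConditions = 5,
                           nTrials = 10, nSamples = 125, srate = 250) {
  stopifnot(inherits(truth, "groundTruth"))
  K <- nrow(truth$plantedMaps)
  nChannels <- ncol(truth$plantedMaps)
  prev <- truth$prevalence
  if (dim(prev)[1] == 1L)
    prev <- array(rep(prev, each = nSubjects),
                  dim = c(nSubjects, dim(prev)[2], K))
  if (dim(prev)[1] != nSubjects) stop("prevalence subjects do not match nSubjects")
  if (dim(prev)[2] != nConditions) stop("prevalence conditions do not match nConditions")
  pos <- if (nChannels == 32) montagePositions() else {
    i <- seq_len(nChannels)
    z <- 1 - (i - 0.5) * (2 / nChannels) * 0.9
    th <- pi * (3 - sqrt(5)) * i
    cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  }
  mixChol <- .noiseMixChol(pos)
  data <- array(0, dim = c(nSubjects, nConditions, nTrials, nChannels, nSamples))
  labels <- array(0L, dim = c(nSubjects, nConditions, nTrials, nSamples))
  p <- 1 / truth$segmentDwell
  for (s in seq_len(nSubjects)) for (c in seq_len(nConditions)) {
    pk <- prev[s, c, ]
    for (tr in seq_len(nTrials)) {
      set.seed(.subSeed(truth$seed, s, c, tr))
      sig <- matrix(0, nChannels, nSamples)
      lab <- integer(nSamples)
      t0 <- 1L
      while (t0 <= nSamples) {
        len <- min(1L + rgeom(1, p), nSamples - t0 + 1L)
        k <- sample.int(K, 1, prob = pk)
        map <- truth$plantedMaps[k, ]
        if (truth$mapJitter > 0)
          map <- normalizeMaps(map + rnorm(nChannels, sd = truth$mapJitter))
        env <- 0.2 + 0.8 * sin(pi * (seq_len(len) - 0.5) / len)
        sgn <- sample(c(-1, 1), 1)
        sig[, t0:(t0 + len - 1L)] <- outer(map, env) * sgn *
          truth$templateAmplitudeUv
        lab[t0:(t0 + len - 1L)] <- k
        t0 <- t0 + len
      }
      noise <- .pinkNoise(nChannels, nSamples, srate, mixChol)
      noise <- noise - rep(colMeans(noise), each = nChannels)  # average reference
      sigRms <- sqrt(mean(sig^2))
      noiseRms <- sqrt(mean(noise^2))
      if (noiseRms > 0)
        noise <- noise * (sigRms / (truth$snr * noiseRms))
      data[s, c, tr, , ] <- sig + noise
      labels[s, c, tr, ] <- lab
    }
  }
  chl <- if (nChannels == 32) rownames(montagePositions()) else
    paste0("Ch", seq_len(nChannels))
  EpochSet(data, chl, srate, c(-nSamples / srate * 1000, 0),
           truth = list(plantedMaps = truth$plantedMaps,
                        prevalence = prev, labels = labels,
                        seed = truth$seed, groundTruth = truth))
}

#' Generate per-subject behavioral metrics
#'
#' Reaction time = 500 ms base + per-condition `rtShift` + a subject effect
#' + noise; movement duration has a subject effect but no condition effect;
#' RMS EMG scales multiplicatively with `emgScale`; pre-movement RMS EMG is
#' small and load-independent. A monotone `emgScale` therefore yields
#' stochastically ordered RMS EMG across conditions.
#'
#' @param truth A `groundTruth` object.
#' @param nSubjects,nConditions Design counts.
#' @param rtNoiseSd,mdNoiseSd Trial-mean noise SDs (ms); 0 gives exact
#'   values.
#' @param emgNoiseCv Coefficient of variation of the EMG noise (0 = exact
#'   scaling).
#' @return A `behavioralTable` data.frame: subject, condition,
#'   reactionTimeMs, movementDurationMs, rmsEmg, preMovementRmsEmg.
#' @export
generateBehavior <- function(truth, nSubjects = 10, nConditions = NULL,
                             rtNoiseSd = 20, mdNoiseSd = 150,
                             emgNoiseCv = 0.1) {
  stopifnot(inherits(truth, "groundTruth"))
  if (is.null(nConditions)) nConditions <- length(truth$rtShift)
  if (nConditions > length(truth$rtShift))
    stop("truth carries fewer conditions than requested")
  set.seed(.subSeed(truth$seed, 7001L))
  subjRt <- rnorm(nSubjects, 0, 30)
  subjMd <- rnorm(nSubjects, 0, 200)
  subjEmg <- exp(rnorm(nSubjects, 0, 0.15))
  rows <- expand.grid(condition = seq_len(nConditions),
                      subject = seq_len(nSubjects))[, c(2, 1)]
  n <- nrow(rows)
  rt <- 500 + truth$rtShift[rows$condition] + subjRt[rows$subject] +
    rnorm(n, 0, rtNoiseSd)
  md <- 2000 + subjMd[rows$subject] + rnorm(n, 0, mdNoiseSd)
  emg <- 50 * truth$emgScale[rows$condition] * subjEmg[rows$subject] *
    (1 + rnorm(n, 0, emgNoiseCv))
  pre <- 5 * subjEmg[rows$subject] * (1 + rnorm(n, 0, emgNoiseCv))
  out <- data.frame(subject = rows$subject, condition = rows$condition,
                    reactionTimeMs = pmax(rt, 50),
                    movementDurationMs = pmax(md, 200),
                    rmsEmg = pmax(emg, 1e-6),
                    preMovementRmsEmg = pmax(pre, 1e-6))
  class(out) <- c("behavioralTable", "data.frame")
  out
}

#' Generate synthetic EMG and kinematic traces with known onsets
#'
#' Builds one condition block: a kinematic flexion-extension trace (trapezoid
#' per trial: rise at movement onset, plateau, fall at offset) sampled at the
#' IMU rate, and a band-limited EMG trace at the EMG rate whose in-movement
#' amplitude scales with the condition's `emgScale`. True onset/offset
#' indices are returned for both sampling rates.
#'
#' @param truth A `groundTruth` object.
#' @param condition Condition index (selects `emgScale` / `rtShift`).
#' @param nTrials Trials in the block.
#' @param trialDurS Trial duration (s), cue at 1 s into each trial.
#' @param srateEmg EMG sampling rate (default 4000).
#' @param srateKin Kinematic sampling rate (default 60).
#' @param kinNoiseSd Additive noise SD on the kinematic trace.
#' @param emgBaseUv Scale of the in-movement EMG amplitude (microvolts).
#' @return List: `kin`, `emg` (numeric traces), `srateKin`, `srateEmg`,
#'   `cues`, `onsets`, `offsets` (kinematic-rate sample indices),
#'   `onsetsEmg`, `offsetsEmg`, `condition`.
#' @export
generateEmgAndOnsets <- function(truth, condition = 1L, nTrials = 10,
                                 trialDurS = 10, srateEmg = 4000,
                                 srateKin = 60, kinNoiseSd = 0.01,
                                 emgBaseUv = 100) {
  stopifnot(inherits(truth, "groundTruth"))
  set.seed(.subSeed(truth$seed, 9000L, condition))
  nKin <- round(nTrials * trialDurS * srateKin)
  nEmg <- round(nTrials * trialDurS * srateEmg)
  kin <- rnorm(nKin, 0, kinNoiseSd)
  cues <- onsets <- offsets <- integer(nTrials)
  for (tr in seq_len(nTrials)) {
    t0 <- (tr - 1) * trialDurS
    cueS <- t0 + 1
    rtS <- (500 + truth$rtShift[condition] + rnorm(1, 0, 20)) / 1000
    onS <- cueS + rtS
    riseS <- 0.5; holdS <- 1.0; fallS <- 0.7
    offS <- onS + riseS + holdS + fallS
    cues[tr] <- round(cueS * srateKin) + 1L
    onsets[tr] <- round(onS * srateKin) + 1L
    offsets[tr] <- round(offS * srateKin) + 1L
    tt <- seq_len(nKin) / srateKin
    ramp <- pmin(pmax((tt - onS) / riseS, 0), 1) *
      pmin(pmax((offS - tt) / fallS, 0), 1)
    kin <- kin + pmin(ramp, 1)
  }
  # EMG: white noise band-passed to 20-450 Hz, amplitude-modulated
  bf <- signal::butter(4, c(20, 450) / (srateEmg / 2), type = "pass")
  carrier <- signal::filtfilt(bf, rnorm(nEmg))
  carrier <- carrier / sqrt(mean(carrier^2))
  amp <- rep(0.05, nEmg)
  onsetsEmg <- round((onsets - 1L) / srateKin * srateEmg) + 1L
  offsetsEmg <- round((offsets - 1L) / srateKin * srateEmg) + 1L
  for (tr in seq_len(nTrials))
    amp[onsetsEmg[tr]:offsetsEmg[tr]] <- truth$emgScale[condition]
  emg <- emgBaseUv * amp * carrier
  list(kin = kin, emg = emg, srateKin = srateKin, srateEmg = srateEmg,
       cues = cues, onsets = onsets, offsets = offsets,
       onsetsEmg = onsetsEmg, offsetsEmg = offsetsEmg,
       condition = condition)
}
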