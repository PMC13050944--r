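# Generator: planted structure, invariants, determinism.

test_that("ground truth enforces its invariants", {
  expect_error(groundTruth(matrix(0, 2, 8), matrix(0.5, 2, 2)),
               "zero-variance")
  maps <- premstates:::.smoothOrthogonalMaps(2, 16, seed = 1)
  expect_error(groundTruth(maps, matrix(c(0.6, 0.6, 0.3, 0.3), 2, 2)),
               "sum to 1")
  expect_error(groundTruth(maps, matrix(0.5, 2, 2), segmentDwell = 0.5),
               "segmentDwell")
  expect_error(groundTruth(maps, matrix(0.5, 2, 2), snr = 0), "snr")
  tr <- groundTruth(maps, matrix(0.5, 2, 2))
  expect_equal(rowMeans(tr$plantedMaps), c(0, 0), tolerance = 1e-12)
  expect_equal(rowSums(tr$plantedMaps^2), c(1, 1), tolerance = 1e-12)
})

test_that("noiseless single-template epochs correlate perfectly with the planted map", {
  maps <- premstates:::.smoothOrthogonalMaps(1, 32, seed = 4)
  tr <- groundTruth(maps, matrix(1, 2, 1), snr = Inf, mapJitter = 0, seed = 4)
  ep <- generateEpochs(tr, nSubjects = 1, nConditions = 2, nTrials = 2)
  pk <- gfpPeakMaps(ep)
  cors <- apply(pk$maps, 1, spatialCorrelation, b = maps[1, ])
  expect_true(all(cors > 1 - 1e-9))
})

test_that("realized label fractions match planted prevalence (binomial bound)", {
  maps <- premstates:::.smoothOrthogonalMaps(2, 32, seed = 9)
  tr <- groundTruth(maps, matrix(0.5, 1, 2), segmentDwell = 12, seed = 9)
  ep <- generateEpochs(tr, nSubjects = 1, nConditions = 1, nTrials = 1,
                       nSamples = 10000)
  lab <- ep@truth$labels[1, 1, 1, ]
  frac <- mean(lab == 1)
  nSeg <- sum(diff(lab) != 0) + 1          # realized segment count
  se <- sqrt(0.25 / nSeg)
  expect_lt(abs(frac - 0.5), 3 * se + 0.02)  # dwell-length variability slack
})

test_that("epoch generation is bit-identical under a fixed seed", {
  tr <- tinyTruth(seed = 21)
  e1 <- tinyEpochs(tr)
  e2 <- tinyEpochs(tr)
  expect_identical(e1@data, e2@data)
  expect_identical(e1@truth$labels, e2@truth$labels)
})

test_that("generated data are average-referenced and finite", {
  ep <- tinyEpochs()
  m <- trialMatrix(ep, 1, 1, 1)
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_true(all(is.finite(ep@data)))
  expect_error(validObject(ep), NA)
})

test_that("noise spectrum decreases with frequency over 1-30 Hz", {
  maps <- premstates:::.smoothOrthogonalMaps(1, 32, seed = 3)
  tr <- groundTruth(maps, matrix(1, 1, 1), snr = 1e-6, seed = 3)
  ep <- generateEpochs(tr, nSubjects = 1, nConditions = 1, nTrials = 20,
                       nSamples = 250)
  # averaged periodogram over trials and channels
  pows <- matrix(0, 20, 125)
  for (tr_ in 1:20) {
    m <- trialMatrix(ep, 1, 1, tr_)
    sp <- Mod(stats::mvfft(t(m)))^2
    pows[tr_, ] <- rowMeans(sp)[2:126]
  }
  p <- colMeans(pows)
  f <- (1:125)
  bandPower <- function(lo, hi) mean(p[f >= lo & f <= hi])
  expect_gt(bandPower(1, 5), bandPower(10, 15))
  expect_gt(bandPower(10, 15), bandPower(25, 30))
})

test_that("behavioral generator plants the requested effects", {
  maps <- premstates:::.smoothOrthogonalMaps(2, 32, seed = 6)
  # rtShift all zero, zero noise: identical RT across conditions
  tr0 <- groundTruth(maps, matrix(0.5, 3, 2), rtShift = c(0, 0, 0),
                     emgScale = c(1, 1, 2), seed = 6)
  b0 <- generateBehavior(tr0, nSubjects = 4, rtNoiseSd = 0, mdNoiseSd = 0,
                         emgNoiseCv = 0)
  for (s in 1:4) {
    rts <- b0$reactionTimeMs[b0$subject == s]
    expect_equal(max(rts) - min(rts), 0)
  }
  # emgScale (1, 2): exact doubling at zero noise
  for (s in 1:4) {
    e <- b0$rmsEmg[b0$subject == s]
    expect_equal(e[3] / e[2], 2, tolerance = 1e-12)
  }
  expect_true(all(b0$reactionTimeMs > 0))
  expect_equal(nrow(b0), 4 * 3)
})

test_that("monotone emgScale yields stochastically ordered RMS EMG", {
  tr <- defaultGroundTruth(K = 2, nConditions = 4, seed = 8,
                           emgScale = c(0.5, 1, 1.5, 2))
  b <- generateBehavior(tr, nSubjects = 10, nConditions = 4)
  m <- vapply(1:4, function(c) mean(b$rmsEmg[b$condition == c]), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("kinematic/EMG block carries recoverable onsets and scalable EMG", {
  tr <- tinyTruth(nConditions = 2, seed = 31)
  blk <- generateEmgAndOnsets(tr, condition = 1, nTrials = 4,
                              kinNoiseSd = 0)
  # trapezoid rises exactly at the planted onset
  ev <- detectOnsets(blk$kin, blk$cues, blk$srateKin,
                     thresholdFraction = 0.1)
  expect_equal(nrow(ev), 4)
  # threshold is reached ~10% into the 0.5 s rise (3 samples at 60 Hz)
  expect_true(all(ev$onset - blk$onsets >= 0 & ev$onset - blk$onsets <= 5))
  # doubling emgScale doubles the in-movement RMS exactly (same carrier)
  tr2 <- groundTruth(tr$plantedMaps, tr$prevalence,
                     emgScale = 2 * tr$emgScale, rtShift = tr$rtShift,
                     seed = tr$seed)
  blk2 <- generateEmgAndOnsets(tr2, condition = 1, nTrials = 4,
                               kinNoiseSd = 0)
  r1 <- sqrt(mean(blk$emg[blk$onsetsEmg[1]:blk$offsetsEmg[1]]^2))
  r2 <- sqrt(mean(blk2$emg[blk2$onsetsEmg[1]:blk2$offsetsEmg[1]]^2))
  expect_equal(r2 / r1, 2, tolerance = 1e-9)
  # determinism
  blk3 <- generateEmgAndOnsets(tr, condition = 1, nTrials = 4,
                               kinNoiseSd = 0)
  expect_identical(blk$onsets, blk3$onsets)
  expect_identical(blk$emg, blk3$emg)
})
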