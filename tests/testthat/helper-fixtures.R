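# Shared fixtures, all built in code.

# small planted-structure truth: K orthogonal maps on the 32-channel montage
tinyTruth <- function(K = 3, nConditions = 2, snr = 5, seed = 11,
                      mapJitter = 0, ...) {
  defaultGroundTruth(K = K, nConditions = nConditions, snr = snr,
                     seed = seed, mapJitter = mapJitter, ...)
}

tinyEpochs <- function(truth = tinyTruth(), nSubjects = 2, nConditions = 2,
                       nTrials = 3, nSamples = 125) {
  generateEpochs(truth, nSubjects = nSubjects, nConditions = nConditions,
                 nTrials = nTrials, nSamples = nSamples)
}

# hand-built neighborhood for interpolation tests: channel 1's neighbors
# are channels 2..4 at chosen distances
manualNeighborhood <- function(nChannels = 4, distances = c(1, 1, 1)) {
  nb <- matrix(rep(2:4, nChannels), nChannels, 3, byrow = TRUE)
  nb[2, ] <- c(1, 3, 4); nb[3, ] <- c(1, 2, 4); nb[4, ] <- c(1, 2, 3)
  d <- matrix(rep(distances, nChannels), nChannels, 3, byrow = TRUE)
  structure(list(neighbors = nb, distances = d,
                 labels = paste0("Ch", seq_len(nChannels))),
            class = "channelNeighborhood")
}

# straight-loop GEV oracle, independent of the package implementation
gevLoopOracle <- function(X, A, labels) {
  X <- as.matrix(X); A <- as.matrix(A)
  num <- rep(0, nrow(A)); den <- 0
  for (t in seq_len(nrow(X))) {
    v <- X[t, ] - mean(X[t, ])
    g <- sqrt(mean(v^2))
    den <- den + g^2
    a <- A[labels[t], ] - mean(A[labels[t], ])
    co <- abs(sum(v * a)) / (sqrt(sum(v^2)) * sqrt(sum(a^2)))
    num[labels[t]] <- num[labels[t]] + (g * co)^2
  }
  list(perMap = num / den, total = sum(num) / den)
}

# one load-effect replicate: 4 load conditions with linearly declining
# prevalence of the effect map, fixed-K two-level fit, Friedman + Dunn on
# the recovered time frames of the map matched to the planted effect map
loadEffectReplicate <- function(seed, nSubjects = 10, nTrials = 5, K = 8,
                                snr = 2, effectMap = 2,
                                prevRange = c(0.25, 0.05), nRestarts = 3) {
  nCond <- 4
  plantedMaps <- premstates:::.smoothOrthogonalMaps(K, 32, seed = seed)
  pEff <- seq(prevRange[1], prevRange[2], length.out = nCond)
  prevalence <- matrix(0, nCond, K)
  for (c in seq_len(nCond)) {
    prevalence[c, ] <- (1 - pEff[c]) / (K - 1)
    prevalence[c, effectMap] <- pEff[c]
  }
  truth <- groundTruth(plantedMaps, prevalence, snr = snr, seed = seed)
  ep <- generateEpochs(truth, nSubjects = nSubjects, nConditions = nCond,
                       nTrials = nTrials)
  subjT <- lapply(seq_len(nSubjects), function(s) {
    pk <- gfpPeakMaps(ep, subjects = s)
    modifiedKmeans(pk$maps, K, nRestarts = nRestarts,
                   seed = premstates:::.subSeed(seed, s, 500L))$templates
  })
  pooled <- do.call(rbind, lapply(subjT, maps))
  final <- modifiedKmeans(pooled, K, nRestarts = nRestarts,
                          seed = premstates:::.subSeed(seed, 501L))$templates
  st <- conditionStats(final, ep)
  hit <- matchMaps(final, plantedMaps)
  m2 <- hit$map[hit$reference == effectMap]
  tf <- matrix(NA_real_, nSubjects, nCond)
  for (c in seq_len(nCond)) {
    sel <- st$map == m2 & st$condition == c
    tf[, c] <- st$timeFrames[sel][order(st$subject[sel])]
  }
  fr <- friedmanTest(tf)
  dn <- dunnPosthoc(tf)
  best <- which.min(dn$pAdjusted)
  list(p = fr$p, chi2 = fr$chi2,
       extremePairBest = dn$i[best] == 1 && dn$j[best] == nCond,
       matchCorr = hit$corr[hit$reference == effectMap],
       meanTf = colMeans(tf))
}

# hash all text outputs of a pipeline report directory
hashReportDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(csv|json|ep)$",
                           full.names = TRUE))
  vapply(files, function(f) unname(tools::md5sum(f)), character(1))
}
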