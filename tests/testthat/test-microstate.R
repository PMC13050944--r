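# GFP, peaks, spatial correlation, modified k-means, GEV.

test_that("gfp matches its defining formula", {
  expect_equal(gfp(rep(4, 10)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  v <- c(0.3, -1.2, 2.5, 0.1, -0.9)
  expect_equal(gfp(v), sqrt(mean((v - mean(v))^2)), tolerance = 1e-14)
  m <- matrix(rnorm(5 * 7), 5)
  expect_equal(gfp(m), apply(m, 2, function(col) gfp(col)), tolerance = 1e-14)
  expect_error(gfp(c(1, NA)), "non-finite")
  expect_error(gfp(3), "2 channels")
})

test_that("GFP peak detection handles plateaus, endpoints and analytic extrema", {
  expect_length(findGfpPeaks(1:10), 0)                 # monotone
  expect_equal(findGfpPeaks(c(0, 1, 0, 2, 0)), c(2, 4))
  expect_equal(findGfpPeaks(c(0, 2, 2, 2, 0)), 2)      # plateau -> first sample
  expect_length(findGfpPeaks(c(3, 1, 1, 3)), 0)        # endpoints never peaks
  g <- abs(sin(2 * pi * 5 * seq(0, 1 - 1e-3, by = 1e-3)))  # 10 arches
  expect_length(findGfpPeaks(g), 10)
})

test_that("spatial correlation is polarity- and scale-invariant", {
  set.seed(1)
  a <- rnorm(32); b <- rnorm(32)
  expect_equal(spatialCorrelation(a, a), 1)
  expect_equal(spatialCorrelation(a, -a), 1)
  expect_equal(spatialCorrelation(a, 5 * b), spatialCorrelation(a, b))
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)             # centered orthogonal
  expect_equal(spatialCorrelation(u, v), 0)
  expect_error(spatialCorrelation(rep(1, 4), v), "zero-variance")
  expect_error(spatialCorrelation(a, rnorm(8)), "channel counts")
})

test_that("modified k-means recovers planted templates despite polarity flips", {
  set.seed(10)
  tpl <- normalizeMaps(matrix(rnorm(2 * 32), 2))
  tpl[2, ] <- normalizeMaps(tpl[2, ] - sum(tpl[2, ] * tpl[1, ]) * tpl[1, ])
  # 60 copies of each template with random polarity
  X <- rbind(tpl[rep(1, 60), ], tpl[rep(2, 60), ]) *
    sample(c(-1, 1), 120, replace = TRUE)
  fit <- modifiedKmeans(X, 2, nRestarts = 5, seed = 3)
  mm <- matchMaps(fit$templates, tpl)
  expect_true(all(mm$corr >= 0.999))
  expect_equal(fit$gev$total, 1, tolerance = 1e-9)
  # single-template degenerate case
  one <- modifiedKmeans(tpl[rep(1, 20), , drop = FALSE], 1, nRestarts = 2,
                        seed = 1)
  expect_gt(abs(spatialCorrelation(maps(one$templates)[1, ], tpl[1, ])), 1 - 1e-9)
})

test_that("modified k-means is deterministic under a seed and ascends in GEV", {
  set.seed(11)
  X <- matrix(rnorm(200 * 32), 200)
  f1 <- modifiedKmeans(X, 4, nRestarts = 5, seed = 99)
  f2 <- modifiedKmeans(X, 4, nRestarts = 5, seed = 99)
  expect_identical(f1$labels, f2$labels)
  expect_identical(maps(f1$templates), maps(f2$templates))
  expect_true(all(diff(f1$gevTrace) > -1e-10))     # monotone ascent
  expect_error(modifiedKmeans(X, 300, seed = 1), "exceeds")
  expect_error(modifiedKmeans(X, 4, nRestarts = 2), "seed")
})

test_that("GEV is exact on noiseless template data and matches a loop oracle", {
  set.seed(12)
  tpl <- normalizeMaps(matrix(rnorm(3 * 16), 3))
  idx <- rep(1:3, each = 30)
  X <- tpl[idx, ] * runif(90, 0.5, 2) * sample(c(-1, 1), 90, TRUE)
  g <- gev(X, tpl, labels = idx)
  expect_equal(g$total, 1, tolerance = 1e-9)
  expect_equal(sum(g$perMap), g$total, tolerance = 1e-12)
  # labels forced onto orthogonal-to-data templates give (near) zero GEV
  Q <- qr.Q(qr(t(tpl)))                     # basis of the data's row space
  raw <- matrix(rnorm(3 * 16), 3)
  raw <- raw - rowMeans(raw)
  orthTpl <- normalizeMaps(raw - raw %*% Q %*% t(Q))
  g0 <- gev(X, orthTpl, labels = idx)
  expect_lt(g0$total, 1e-20)
  # random data vs straight-loop oracle
  Y <- matrix(rnorm(40 * 16), 40)
  fit <- modifiedKmeans(Y, 2, nRestarts = 3, seed = 5)
  gp <- gev(Y, fit$templates, fit$labels)
  oracle <- gevLoopOracle(Y, maps(fit$templates), fit$labels)
  expect_equal(gp$total, oracle$total, tolerance = 1e-10)
  expect_equal(gp$perMap, oracle$perMap, tolerance = 1e-10)
  expect_true(gp$total >= 0 && gp$total <= 1)
  expect_error(gev(matrix(0, 5, 8), tpl[, 1:8]), "zero")
})

test_that("clustering is polarity-invariant and channel-permutation equivariant", {
  set.seed(13)
  tr <- tinyTruth(K = 3, seed = 33)
  ep <- tinyEpochs(tr, nSubjects = 1, nTrials = 2)
  pk <- gfpPeakMaps(ep, subjects = 1)
  fit <- modifiedKmeans(pk$maps, 3, nRestarts = 5, seed = 7)
  # negating an arbitrary subset of maps changes nothing
  flip <- sample(c(-1, 1), nrow(pk$maps), replace = TRUE)
  fitF <- modifiedKmeans(pk$maps * flip, 3, nRestarts = 5, seed = 7)
  expect_identical(fit$labels, fitF$labels)
  expect_equal(fit$gev$total, fitF$gev$total, tolerance = 1e-12)
  expect_equal(abs(maps(fit$templates)), abs(maps(fitF$templates)),
               tolerance = 1e-9)
  # permuting channels permutes templates identically
  perm <- sample(ncol(pk$maps))
  fitP <- modifiedKmeans(pk$maps[, perm], 3, nRestarts = 5, seed = 7)
  expect_identical(fit$labels, fitP$labels)
  expect_equal(maps(fitP$templates), maps(fit$templates)[, perm],
               tolerance = 1e-7)
})

test_that("validity criteria select the planted K and the median rule holds", {
  expect_equal(premstates:::.lowerMedian(c(3, 4, 4, 5, 6, 7, 8)), 5)
  expect_equal(premstates:::.lowerMedian(c(4, 4, 4)), 4)
  expect_equal(premstates:::.lowerMedian(c(4, 6)), 4)   # tie -> smaller K
  hits <- 0L
  for (seed in 1:3) {
    tr <- tinyTruth(K = 4, snr = 4, seed = 100 + seed)
    ep <- generateEpochs(tr, nSubjects = 1, nConditions = 2, nTrials = 4)
    pk <- gfpPeakMaps(ep, subjects = 1)
    fits <- lapply(2:8, function(K)
      modifiedKmeans(pk$maps, K, nRestarts = 5, seed = K))
    names(fits) <- 2:8
    mc <- validityCriteria(fits, pk$maps)
    expect_s3_class(mc, "metaCriterion")
    expect_true(mc$metaK %in% 2:8)
    if (mc$metaK == 4) hits <- hits + 1L
  }
  expect_gte(hits, 2L)    # majority over seeds
})

test_that("TemplateSet construction normalizes and validates", {
  m <- matrix(rnorm(3 * 16), 3)
  ts <- TemplateSet(m)
  expect_equal(rowMeans(maps(ts)), rep(0, 3), tolerance = 1e-12)
  expect_equal(rowSums(maps(ts)^2), rep(1, 3), tolerance = 1e-12)
  expect_equal(nMaps(ts), 3)
  expect_error(TemplateSet(matrix(rnorm(20 * 16), 20)), "K")
})
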