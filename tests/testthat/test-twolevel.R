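# Two-level procedure: within/across-subject templates, backfitting,
# per-condition statistics.

test_that("identical subjects produce identical template sets (up to order/polarity)", {
  tr <- tinyTruth(K = 3, seed = 51)
  ep1 <- generateEpochs(tr, nSubjects = 1, nConditions = 2, nTrials = 3)
  # duplicate the single subject
  d <- ep1@data
  dd <- array(0, dim = c(2, dim(d)[2:5]))
  dd[1, , , , ] <- d[1, , , , ]; dd[2, , , , ] <- d[1, , , , ]
  ep2 <- EpochSet(dd, ep1@channelLabels, ep1@srate, ep1@epochWindow)
  w <- withinSubjectTemplates(ep2, kRange = 2:5, seed = 5, nRestarts = 5)
  expect_equal(w[[1]]$meta$metaK, w[[2]]$meta$metaK)
  mm <- matchMaps(w[[1]]$templates, w[[2]]$templates)
  expect_true(all(mm$corr > 1 - 1e-6))
})

test_that("subjects with too few GFP peaks are reported by name", {
  tr <- tinyTruth(K = 2, nConditions = 1, seed = 52)
  ep <- generateEpochs(tr, nSubjects = 1, nConditions = 1, nTrials = 1,
                       nSamples = 16)
  expect_error(withinSubjectTemplates(ep, kRange = 2:12, seed = 1),
               "subject 1")
})

test_that("backfitting is exact on template data and polarity-invariant", {
  set.seed(53)
  tpl <- TemplateSet(matrix(rnorm(3 * 32), 3))
  X <- maps(tpl)[rep(1:3, each = 10), ]
  seg <- backfit(tpl, X)
  expect_true(all(seg@corr > 1 - 1e-9))
  expect_equal(seg@labels, rep(1:3, each = 10))
  segF <- backfit(tpl, -X)
  expect_identical(seg@labels, segF@labels)
  # orthogonal-to-data templates: labels defined, corr ~ 0
  Q <- qr.Q(qr(t(maps(tpl))))
  raw <- matrix(rnorm(3 * 32), 3); raw <- raw - rowMeans(raw)
  orth <- TemplateSet(raw - raw %*% Q %*% t(Q))
  segO <- backfit(orth, X)
  expect_true(all(!is.na(segO@labels)))
  expect_lt(max(segO@corr), 1e-6)
  # optional minimum-correlation gate leaves samples unassigned
  segG <- backfit(orth, X, minCorr = 0.5)
  expect_true(all(is.na(segG@labels)))
})

test_that("single-subject across-level pooling reduces to the subject's set", {
  tpl <- TemplateSet(matrix(rnorm(4 * 32), 4))
  out <- acrossSubjectTemplates(list(tpl), kRange = 2:6, seed = 1)
  expect_identical(maps(out$templates), maps(tpl))
})

test_that("shared templates across subjects are recovered at the shared K", {
  set.seed(54)
  tpl <- TemplateSet(matrix(rnorm(3 * 32), 3))
  # every subject contributes the same 3 maps, random polarity
  subj <- lapply(1:5, function(s)
    TemplateSet(maps(tpl) * sample(c(-1, 1), 3, replace = TRUE)))
  out <- acrossSubjectTemplates(subj, kRange = 2:6, seed = 9, nRestarts = 5)
  expect_equal(out$meta$metaK, 3)
  mm <- matchMaps(out$templates, tpl)
  expect_true(all(mm$corr > 1 - 1e-9))
})

test_that("condition statistics conserve time frames and respect purity", {
  tr <- tinyTruth(K = 3, seed = 55)
  ep <- tinyEpochs(tr, nSubjects = 2, nConditions = 2, nTrials = 3)
  final <- TemplateSet(tr$plantedMaps)
  st <- conditionStats(final, ep)
  expect_s3_class(st, "data.frame")
  # conservation: per cell, time frames sum to the labeled sample count
  for (s in 1:2) for (c in 1:2) {
    seg <- backfit(final, ep, subjects = s, conditions = c)
    tfSum <- sum(st$timeFrames[st$subject == s & st$condition == c])
    expect_equal(tfSum, sum(!is.na(seg@labels)))
    expect_equal(sum(st$occurrence[st$subject == s & st$condition == c]), 1,
                 tolerance = 1e-12)
  }
  expect_true(all(st$gev >= 0 & st$gev <= 1))
  # an epoch set built purely from map 1 loads only cell entries for map 1
  one <- groundTruth(tr$plantedMaps,
                     matrix(c(1, 0, 0), 1, 3), snr = 100, mapJitter = 0,
                     seed = 7)
  epPure <- generateEpochs(one, nSubjects = 1, nConditions = 1, nTrials = 2)
  stP <- conditionStats(final, epPure)
  expect_equal(sum(stP$timeFrames[stP$map != 1]), 0)
  expect_gt(stP$gev[stP$map == 1], 0.9)
})

test_that("two-level pipeline is polarity- and channel-permutation invariant end-to-end", {
  tr <- tinyTruth(K = 3, seed = 56)
  ep <- tinyEpochs(tr, nSubjects = 2, nConditions = 2, nTrials = 2)
  run <- function(e) {
    w <- withinSubjectTemplates(e, kRange = 2:5, seed = 3, nRestarts = 4)
    a <- acrossSubjectTemplates(w, kRange = 2:5, seed = 4, nRestarts = 4)
    conditionStats(a$templates, e)
  }
  st0 <- run(ep)
  # negate a subset of epochs
  epN <- ep
  epN@data[1, 1, , , ] <- -epN@data[1, 1, , , ]
  epN@data[2, 2, 1, , ] <- -epN@data[2, 2, 1, , ]
  stN <- run(epN)
  expect_equal(st0$timeFrames, stN$timeFrames)
  expect_equal(st0$gev, stN$gev, tolerance = 1e-10)
  # permute channels consistently
  perm <- sample(32)
  epP <- EpochSet(ep@data[, , , perm, , drop = FALSE],
                  ep@channelLabels[perm], ep@srate, ep@epochWindow)
  stP <- run(epP)
  expect_equal(st0$timeFrames, stP$timeFrames)
  expect_equal(st0$gev, stP$gev, tolerance = 1e-10)
})
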