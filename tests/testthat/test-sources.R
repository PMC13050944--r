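# Spherical lead field, sLORETA inverse, SnPM permutation contrast.

lfSmall <- buildLeadfield(gridSpacingMm = 20, gridRadiusMm = 60)

test_that("shell transfer reduces to the homogeneous closed form", {
  n <- 1:40
  tn <- premstates:::.shellTransfer(40, c(80, 85) / 92, rep(0.33, 3))
  expect_equal(tn, (2 * n + 1) / n, tolerance = 1e-10)
})

test_that("the Legendre series matches the infinite-medium dipole potential", {
  # with no boundary terms the series must equal the direct dipole formula
  set.seed(8)
  p <- c(0.3, 0.2, 0.33); b <- sqrt(sum(p^2)); bh <- p / b
  for (i in 1:5) {
    e <- rnorm(3); e <- e / sqrt(sum(e^2))
    q <- rnorm(3)
    d <- e - p
    direct <- sum(q * d) / (4 * pi * sum(d^2)^1.5)
    N <- 80
    leg <- premstates:::.legendreTables(sum(e * bh), N)
    proj <- e - sum(e * bh) * bh; th <- proj / sqrt(sum(proj^2))
    qr_ <- sum(q * bh); qt <- sum(q * th)
    nn <- seq_len(N)
    series <- sum(b^(nn - 1) * (nn * qr_ * leg$P[, 1] - qt * leg$P1[, 1])) /
      (4 * pi)
    expect_equal(series, direct, tolerance = 1e-8)
  }
})

test_that("lead field rows are average-referenced with sane columns", {
  G <- lfSmall@gain
  expect_lt(max(abs(colMeans(G))), 1e-10)
  expect_true(all(is.finite(G)))
  expect_true(all(sqrt(colSums(G^2)) > 0))
  expect_error(buildLeadfield(gridRadiusMm = 90), "inside")
})

test_that("a central dipole produces a pure dipolar (P1) scalp pattern", {
  lfC <- buildLeadfield(gridSpacingMm = 1000, gridRadiusMm = 1)  # single voxel at origin
  expect_equal(nVoxels(lfC), 1)
  u <- montagePositions()
  for (o in 1:3) {
    g <- lfC@gain[, o]
    cosg <- u[, o]
    # after average reference both are centered; correlation must be 1
    expect_gt(abs(stats::cor(g, cosg - mean(cosg))), 1 - 1e-9)
  }
})

test_that("sLORETA has zero localization error for noiseless grid dipoles", {
  set.seed(9)
  vv <- sample(nVoxels(lfSmall), 10)
  for (v in vv) {
    o <- sample(1:3, 1)
    mapv <- lfSmall@gain[, 3 * (v - 1) + o]
    est <- sloretaInverse(lfSmall, mapv)
    expect_equal(which.max(est@power), v)
  }
})

test_that("sLORETA standardized power is quadratic in the map scale", {
  set.seed(10)
  mapv <- lfSmall@gain[, 10]
  e1 <- sloretaInverse(lfSmall, mapv)
  e3 <- sloretaInverse(lfSmall, 3 * mapv)
  expect_equal(e3@power, 9 * e1@power, tolerance = 1e-8)
  e0 <- sloretaInverse(lfSmall, rep(0, 32))
  expect_equal(max(e0@power), 0)
})

test_that("the minimum-norm stage (pre-standardization) is linear", {
  G <- lfSmall@gain
  C <- nrow(G)
  alpha <- 1e-2 * mean(diag(tcrossprod(G)))
  Tm <- crossprod(G, solve(tcrossprod(G) + alpha * diag(C)))
  m1 <- G[, 5]; m2 <- G[, 50]
  j12 <- Tm %*% (2 * m1 + 3 * m2)
  expect_equal(drop(j12), drop(2 * Tm %*% m1 + 3 * Tm %*% m2),
               tolerance = 1e-9)
})

test_that("rank-deficient unregularized systems are rejected with advice", {
  lfTiny <- buildLeadfield(gridSpacingMm = 60, gridRadiusMm = 60)
  expect_lt(3 * nVoxels(lfTiny), 31)       # fewer sources than channels - 1
  expect_error(sloretaInverse(lfTiny, rnorm(32), alpha = 0),
               "alpha > 0")
})

test_that("SnPM enumeration rule, null behavior, and planted detection", {
  set.seed(11)
  a <- matrix(rnorm(10 * 60), 10)
  r <- snpmPairedContrast(a, a, nPermutations = 5000, seed = 1)
  expect_equal(r$nPermutations, 1024)      # 2^10 < 5000 -> full enumeration
  expect_equal(sum(r$significant), 0)      # identical conditions
  # sampled branch when 2^n is large
  b14 <- matrix(rnorm(14 * 20), 14)
  r14 <- snpmPairedContrast(b14, b14 + 0, nPermutations = 500, seed = 2)
  expect_equal(r14$nPermutations, 500)
  # planted focal effect (Cohen's d = 2 on the paired difference, whose
  # sd is sqrt(2)) in 5% of voxels is detected
  eff <- matrix(rnorm(10 * 100), 10)
  eff[, 1:5] <- eff[, 1:5] + 2 * sqrt(2)
  rp <- snpmPairedContrast(eff, matrix(rnorm(10 * 100), 10),
                           nPermutations = 5000, seed = 3)
  expect_gte(sum(rp$significant[1:5]), 3)
  expect_lte(sum(rp$significant[6:100]), 2)
})
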