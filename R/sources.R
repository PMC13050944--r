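## Simplified distributed source analysis: analytic three-shell spherical
## lead field (Legendre series, per-degree boundary-condition solve),
## sLORETA standardized inverse, and paired sign-flip max-statistic
## permutation contrasts.

## Legendre P_n and associated P_n^1 (Condon-Shortley), n = 1..N, at x
.legendreTables <- function(x, N) {
  L <- length(x)
  P <- matrix(0, N, L); P1 <- matrix(0, N, L)
  Pm2 <- rep(1, L); Pm1 <- x                       # P_0, P_1
  P[1, ] <- x
  s <- -sqrt(pmax(0, 1 - x^2))
  P1m2 <- rep(0, L); P1m1 <- s                     # P_0^1, P_1^1
  P1[1, ] <- s
  for (n in 2:N) {
    Pn <- ((2 * n - 1) * x * Pm1 - (n - 1) * Pm2) / n
    P[n, ] <- Pn; Pm2 <- Pm1; Pm1 <- Pn
    P1n <- ((2 * n - 1) * x * P1m1 - n * P1m2) / (n - 1)
    P1[n, ] <- P1n; P1m2 <- P1m1; P1m1 <- P1n
  }
  list(P = P, P1 = P1)
}

## per-degree radial transfer coefficient t_n = f3(1) for a unit source
## term 1/r^(n+1) in the innermost shell; radii normalized so the outer
## (scalp) radius is 1
.shellTransfer <- function(N, radii, sigmas) {
  r1 <- radii[1]; r2 <- radii[2]
  s1 <- sigmas[1]; s2 <- sigmas[2]; s3 <- sigmas[3]
  t_n <- numeric(N)
  for (n in seq_len(N)) {
    # unknowns: A1, A2, B2, A3, B3
    A <- matrix(0, 5, 5); b <- numeric(5)
    rn <- function(r) r^n; rm <- function(r) r^-(n + 1)
    dn <- function(r) n * r^(n - 1); dm <- function(r) -(n + 1) * r^-(n + 2)
    # continuity of V at r1:  A1 r1^n - A2 r1^n - B2 r1^-(n+1) = -r1^-(n+1)
    A[1, ] <- c(rn(r1), -rn(r1), -rm(r1), 0, 0);  b[1] <- -rm(r1)
    # continuity of sigma dV/dr at r1
    A[2, ] <- c(s1 * dn(r1), -s2 * dn(r1), -s2 * dm(r1), 0, 0)
    b[2] <- -s1 * dm(r1)
    # continuity of V at r2
    A[3, ] <- c(0, rn(r2), rm(r2), -rn(r2), -rm(r2)); b[3] <- 0
    # continuity of sigma dV/dr at r2
    A[4, ] <- c(0, s2 * dn(r2), s2 * dm(r2), -s3 * dn(r2), -s3 * dm(r2))
    b[4] <- 0
    # insulating outer boundary at r = 1
    A[5, ] <- c(0, 0, 0, dn(1), dm(1)); b[5] <- 0
    sol <- solve(A, b)
    t_n[n] <- sol[4] + sol[5]                     # f3(1) = A3 + B3
  }
  t_n
}

#' Analytic three-shell spherical lead field on a regular voxel grid
#'
#' Concentric brain/skull/scalp conductor. Electrodes sit on the outer
#' sphere at the idealized montage directions; each voxel carries three
#' orthogonal unit dipoles. The scalp potential is the Legendre series with
#' per-degree transfer coefficients obtained by solving the interface
#' boundary conditions, and every gain column is average-referenced.
#'
#' @param montage Electrode unit directions (rows), e.g.
#'   [montagePositions()].
#' @param gridSpacingMm Voxel grid spacing (default 12 mm).
#' @param gridRadiusMm Grid points are kept within this radius (default
#'   60 mm; must be inside the brain shell).
#' @param radiiMm Outward radii of brain, skull, scalp shells (mm).
#' @param conductivities Shell conductivities (S/m); the default 1:1/80:1
#'   skull contrast is conventional.
#' @param nTerms Series truncation (default 60).
#' @return A [LeadField-class].
#' @export
buildLeadfield <- function(montage = montagePositions(), gridSpacingMm = 12,
                           gridRadiusMm = 60,
                           radiiMm = c(80, 85, 92),
                           conductivities = c(0.33, 0.0042, 0.33),
                           nTerms = 60) {
  if (gridRadiusMm >= radiiMm[1])
    stop("voxel grid must lie strictly inside the innermost (brain) shell")
  u <- montage / sqrt(rowSums(montage^2))
  # origin-centred grid so the sphere centre is always a lattice point
  g <- sort(unique(c(seq(0, -gridRadiusMm, by = -gridSpacingMm),
                     seq(0, gridRadiusMm, by = gridSpacingMm))))
  vox <- as.matrix(expand.grid(x = g, y = g, z = g))
  vox <- vox[sqrt(rowSums(vox^2)) <= gridRadiusMm, , drop = FALSE]
  V <- nrow(vox)
  scal <- radiiMm[3]
  t_n <- .shellTransfer(nTerms, radii = radiiMm[1:2] / scal,
                        sigmas = conductivities)
  gain <- matrix(0, nrow(u), 3L * V)
  for (v in seq_len(V)) {
    p <- vox[v, ] / scal                      # dipole position, scalp radii
    cols <- (3L * (v - 1L) + 1L):(3L * v)
    gain[, cols] <- .sphericalGainVoxel(u, p, t_n, conductivities[1], scal)
  }
  gain <- gain - rep(colMeans(gain), each = nrow(gain))
  lbl <- rownames(montage)
  if (is.null(lbl)) lbl <- paste0("Ch", seq_len(nrow(u)))
  new("LeadField", gain = gain, voxels = vox, radii = radiiMm,
      conductivities = conductivities, channelLabels = lbl)
}

## channels x 3 gain block for one voxel; u: electrode unit directions,
## p: dipole position in scalp-radius units, t_n: shell transfer terms
.sphericalGainVoxel <- function(u, p, t_n, sigma1, scalpRadiusMm) {
  N <- length(t_n)
  ne <- nrow(u)
  b <- sqrt(sum(p^2))
  out <- matrix(0, ne, 3)
  c0 <- 1 / (4 * pi * sigma1 * (scalpRadiusMm / 1000)^2)  # SI scaling
  if (b < 1e-12) {
    # central dipole: pure n = 1 term, potential ~ cos(angle to moment)
    for (o in 1:3) {
      q <- c(0, 0, 0); q[o] <- 1
      cosg <- drop(u %*% q)
      out[, o] <- c0 * t_n[1] * cosg
    }
    return(out)
  }
  bh <- p / b
  cosg <- drop(u %*% bh)
  cosg <- pmin(1, pmax(-1, cosg))
  leg <- .legendreTables(cosg, N)
  bpow <- b^(seq_len(N) - 1)
  # tangential unit vector at the dipole, toward each electrode
  proj <- u - outer(cosg, bh)
  pn <- sqrt(rowSums(proj^2))
  th <- proj / pmax(pn, 1e-12)
  radialKernel <- colSums(bpow * t_n * (seq_len(N) * leg$P))    # length ne
  tangKernel <- -colSums(bpow * t_n * leg$P1)                   # length ne
  for (o in 1:3) {
    q <- c(0, 0, 0); q[o] <- 1
    qr <- sum(q * bh)
    qt <- drop(th %*% q)                      # th rows are orthogonal to bh
    out[, o] <- c0 * (qr * radialKernel + qt * tangKernel)
  }
  out
}

#' sLORETA standardized inverse solution
#'
#' Computes the regularized minimum-norm solution
#' `j = G' (G G' + alpha H)^+ v` (H = average-reference operator) and
#' standardizes each voxel's 3-vector by the corresponding 3 x 3 diagonal
#' block of the resolution matrix `R = T G`, giving the standardized power
#' `j_v' R_vv^{-1} j_v`. For noiseless single-dipole scalp maps the power
#' maximum falls on the generating voxel (zero localization error).
#'
#' @param leadfield A [LeadField-class].
#' @param map Scalp potential vector (one value per channel);
#'   average-referenced internally.
#' @param alpha Regularization; `"auto"` uses 1e-2 times the mean
#'   eigenvalue of `G G'`.
#' @return A [SourceEstimate-class].
#' @export
sloretaInverse <- function(leadfield, map, alpha = "auto") {
  stopifnot(is(leadfield, "LeadField"))
  G <- leadfield@gain
  C <- nrow(G)
  if (length(map) != C) stop("map length must match channel count")
  v <- map - mean(map)
  GG <- tcrossprod(G)
  if (identical(alpha, "auto")) alpha <- 1e-2 * mean(diag(GG))
  if (alpha < 0) stop("alpha must be >= 0")
  H <- diag(C) - matrix(1 / C, C, C)
  M <- GG + alpha * H
  e <- eigen(M, symmetric = TRUE)
  tolv <- max(e$values) * 1e-12
  pos <- e$values > tolv
  if (sum(pos) < C - 1L)
    stop("rank-deficient system; use alpha > 0")
  Minv <- e$vectors[, pos] %*% (t(e$vectors[, pos]) / e$values[pos])
  Tm <- crossprod(G, Minv)                  # 3V x C
  j <- drop(Tm %*% v)
  V <- nrow(leadfield@voxels)
  power <- numeric(V)
  for (vv in seq_len(V)) {
    cols <- (3L * (vv - 1L) + 1L):(3L * vv)
    Rvv <- Tm[cols, , drop = FALSE] %*% G[, cols, drop = FALSE]
    Rvv <- (Rvv + t(Rvv)) / 2
    jv <- j[cols]
    ev <- eigen(Rvv, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-10
    y <- crossprod(ev$vectors[, keep, drop = FALSE], jv)
    power[vv] <- sum(y^2 / ev$values[keep])
  }
  new("SourceEstimate", power = power, voxels = leadfield@voxels)
}

#' Paired contrast of source estimates with SnPM max-statistic correction
#'
#' Voxel-wise paired t statistics on the per-subject difference images,
#' with the family-wise null built by random sign flips of the differences.
#' The corrected threshold is the `(1 - alpha)` quantile of the max-|t|
#' distribution. When the requested number of permutations exceeds `2^n`,
#' the complete enumeration of all `2^n` sign patterns is used instead.
#'
#' @param a,b subjects x voxels matrices (or lists of
#'   [SourceEstimate-class]) for the two conditions, same subject order.
#' @param nPermutations Requested permutations (default 5000).
#' @param alpha Family-wise level (default 0.05).
#' @param seed Seed for sampled sign flips.
#' @return An `snpmResult` list: `t` (observed per voxel), `tCrit`,
#'   `pCorrected`, `significant`, `nPermutations` (used), `maxDistribution`.
#' @export
snpmPairedContrast <- function(a, b, nPermutations = 5000, alpha = 0.05,
                               seed = 1L) {
  toMat <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, function(e) e@power)) else as.matrix(x)
  }
  A <- toMat(a); B <- toMat(b)
  if (!all(dim(A) == dim(B))) stop("a and b must have identical dimensions")
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 subjects")
  D <- A - B
  if (2^n <= nPermutations) {
    P <- 2^n
    S <- matrix(1, P, n)
    for (i in seq_len(n))
      S[, i] <- rep(rep(c(1, -1), each = 2^(n - i)), length.out = P)
  } else {
    set.seed(as.integer(seed))
    P <- nPermutations
    S <- matrix(sample(c(1, -1), P * n, replace = TRUE), P, n)
    S[1, ] <- 1                               # include the identity
  }
  means <- (S %*% D) / n
  msq <- colMeans(D^2)
  vars <- sweep(-means^2, 2, msq, "+") * n / (n - 1)
  vars[vars < 1e-24] <- 1e-24
  tAll <- means / sqrt(vars / n)
  tObs <- if (all(S[1, ] == 1)) tAll[1, ] else {
    m <- colMeans(D); m / sqrt(apply(D, 2, var) / n)
  }
  maxAbs <- apply(abs(tAll), 1, max)
  tCrit <- sort(maxAbs)[ceiling((1 - alpha) * P)]
  pCorr <- vapply(abs(tObs), function(t0) mean(maxAbs >= t0 - 1e-12),
                  numeric(1))
  structure(list(t = tObs, tCrit = tCrit, pCorrected = pCorr,
                 significant = pCorr <= alpha, nPermutations = P,
                 maxDistribution = maxAbs),
            class = "snpmResult")
}

#' @export
print.snpmResult <- function(x, ...) {
  cat(sprintf("SnPM paired contrast: %d permutations, t_crit = %.3f\n",
              x$nPermutations, x$tCrit))
  cat(sprintf("  %d of %d voxels suprathreshold\n",
              sum(x$significant), length(x$t)))
  invisible(x)
}
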