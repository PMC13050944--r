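## Core topographic machinery: GFP, GFP-peak detection, polarity-invariant
## spatial correlation, modified k-means, GEV.
##
## Orientation conventions:
##   * a single trial is a channels x samples matrix;
##   * a set of observed topographies ("maps") is rows = maps (M x channels).

#' Center topographies and scale them to unit norm
#'
#' Applies the average reference across channels to every row and divides by
#' the L2 norm, the canonical form for polarity-invariant comparison.
#'
#' @param x Numeric matrix, one topography per row, or a single numeric
#'   vector.
#' @return Matrix (or vector) of the same shape with zero row means and unit
#'   row norms.
#' @export
normalizeMaps <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm < 1e-300))
    stop("cannot normalize a zero-variance topography")
  x <- x / nrm
  if (vec) drop(x) else x
}

#' Global field power
#'
#' The spatial standard deviation of the scalp potential about the channel
#' mean: `sqrt(mean((v - mean(v))^2))`. For a channels x samples matrix, one
#' value per sample (column) is returned.
#'
#' @param x Numeric vector (one topography) or channels x samples matrix.
#' @return Non-negative scalar, or vector of per-sample GFP values.
#' @examples
#' gfp(c(1, -1))        # 1
#' gfp(rep(3, 10))      # 0
#' @export
gfp <- function(x) {
  if (any(!is.finite(x))) stop("gfp: non-finite input")
  if (is.null(dim(x))) {
    if (length(x) < 2L) stop("gfp needs at least 2 channels")
    return(sqrt(mean((x - mean(x))^2)))
  }
  if (nrow(x) < 2L) stop("gfp needs at least 2 channels")
  cm <- colMeans(x)
  sqrt(colMeans((x - rep(cm, each = nrow(x)))^2))
}

#' Locate local maxima of a GFP series
#'
#' A peak is a strict local maximum `g[t-1] < g[t] > g[t+1]`. A plateau of
#' equal values that stands above both flanks is resolved to its first
#' sample. Series endpoints are never peaks.
#'
#' @param g Numeric GFP series (length >= 3).
#' @return Integer vector of peak indices (possibly empty).
#' @examples
#' findGfpPeaks(c(0, 1, 0, 2, 0))  # 2 and 4
#' @export
findGfpPeaks <- function(g) {
  n <- length(g)
  if (n < 3L) stop("series too short for peak detection")
  r <- rle(g)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  isPeak <- logical(k)
  isPeak[2:(k - 1)] <- r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                       r$values[2:(k - 1)] > r$values[3:k]
  starts[isPeak]
}

#' Polarity-invariant spatial correlation between two topographies
#'
#' Absolute Pearson correlation across channels of the average-referenced
#' maps (equivalently, the absolute cosine after centering). Invariant to
#' polarity and scale by construction.
#'
#' @param a,b Numeric vectors of equal length (one value per channel).
#' @return A value in `[0, 1]`.
#' @export
spatialCorrelation <- function(a, b) {
  if (length(a) != length(b)) stop("channel counts differ")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-300 || nb < 1e-300)
    stop("zero-variance topography has no defined spatial correlation")
  min(1, abs(sum(a * b)) / (na * nb))
}

## absolute correlation of each row of X (M x C, centered) with each row of
## template matrix A (K x C, centered & unit norm); returns M x K
.absCorrMatrix <- function(X, A) {
  Xn <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xn^2))
  nrm[nrm < 1e-300] <- 1
  Xn <- Xn / nrm
  cc <- abs(tcrossprod(Xn, A))
  cc[cc > 1] <- 1
  cc
}

## polarity-invariant centroid: dominant eigenvector of sum of outer
## products of the (raw, centered) member maps
.dominantMap <- function(Xk) {
  S <- crossprod(Xk)             # C x C
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("degenerate cluster: zero dominant map")
  v <- v / n
  # deterministic sign convention: largest-|.| channel positive
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

## warm-started power iteration on the PSD scatter matrix; the Rayleigh
## quotient (cluster GEV contribution) is non-decreasing from the start
## vector, preserving the monotone-ascent property of the k-means update
.dominantMapFrom <- function(Xk, a0, iters = 40L, tol = 1e-10) {
  S <- crossprod(Xk)
  v <- a0
  for (i in seq_len(iters)) {
    w <- drop(S %*% v)
    n <- sqrt(sum(w^2))
    if (n < 1e-300) return(.dominantMap(Xk))
    w <- w / n
    if (sum(abs(w - v)) < tol || sum(abs(w + v)) < tol) { v <- w; break }
    v <- w
  }
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("degenerate cluster: zero dominant map")
  v <- v / n
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Modified (polarity-invariant) k-means clustering of topographies
#'
#' Alternates (i) assignment of every map to the template with the highest
#' absolute spatial correlation and (ii) template update as the dominant
#' eigenvector of the outer-product sum of the assigned maps, until the
#' labeling stabilizes or the relative GEV change falls below `tol`. This
#' alternation never decreases GEV, so the best restart (by GEV) is a local
#' optimum of explained variance. Ties in assignment break to the lower
#' template index; an emptied cluster is reseeded from the worst-fit map.
#'
#' @param x M x channels matrix of observed topographies (rows). They are
#'   average-referenced internally; their GFP is used to weight GEV, so raw
#'   (unnormalized) maps are acceptable and give the classical GFP-weighted
#'   fit.
#' @param k Number of templates, `1 <= k <= min(M, channels)`.
#' @param nRestarts Random restarts; the restart attaining the highest GEV
#'   wins (default 20).
#' @param tol Relative GEV convergence tolerance (default 1e-6).
#' @param maxIter Iteration cap per restart.
#' @param seed Integer seed (required: results are deterministic given it).
#' @return A list with `templates` ([TemplateSet-class]), `labels`, `corr`
#'   (per input map), `gev` (list `perMap`, `total`), `iterations`.
#' @export
modifiedKmeans <- function(x, k, nRestarts = 20L, tol = 1e-6,
                           maxIter = 100L, seed) {
  if (missing(seed)) stop("modifiedKmeans requires an explicit seed")
  x <- as.matrix(x)
  M <- nrow(x); C <- ncol(x)
  if (k > M) stop("k exceeds the number of observed maps")
  if (k < 1L) stop("k must be >= 1")
  Xc <- x - rowMeans(x)
  g <- sqrt(rowMeans(Xc^2))          # per-map GFP
  denom <- sum(g^2)
  if (denom <= 0) stop("all maps have zero GFP")
  nrm <- sqrt(rowSums(Xc^2)); nrm[nrm < 1e-300] <- 1
  Xn <- Xc / nrm                     # normalized once, reused every iteration
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); code
  }
  best <- NULL
  runOne <- function() {
    A <- Xc[sample.int(M, k), , drop = FALSE]
    A <- normalizeMaps(A)
    labels <- rep(0L, M); lastGev <- -Inf; it <- 0L; trace <- numeric(0)
    repeat {
      it <- it + 1L
      cc <- abs(tcrossprod(Xn, A)); cc[cc > 1] <- 1
      newLabels <- max.col(cc, ties.method = "first")
      corr <- cc[cbind(seq_len(M), newLabels)]
      for (j in seq_len(k)) {                 # reseed empty clusters
        if (!any(newLabels == j)) {
          w <- which.min(corr)
          newLabels[w] <- j
          corr[w] <- 1
        }
      }
      for (j in seq_len(k))
        A[j, ] <- .dominantMapFrom(Xc[newLabels == j, , drop = FALSE], A[j, ])
      cc <- abs(tcrossprod(Xn, A)); cc[cc > 1] <- 1
      corr <- cc[cbind(seq_len(M), newLabels)]
      gevNow <- sum((g * corr)^2) / denom
      trace <- c(trace, gevNow)
      done <- identical(newLabels, labels) ||
        (gevNow - lastGev) < tol * max(lastGev, .Machine$double.eps) ||
        it >= maxIter
      labels <- newLabels; lastGev <- gevNow
      if (done) break
    }
    list(A = A, labels = labels, corr = corr, gev = lastGev, it = it,
         trace = trace)
  }
  withr_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      run <- runOne()
      # margin keeps the winner stable under floating-point reordering
      # (e.g. consistent channel permutations of the input)
      if (is.null(best) || run$gev > best$gev + 1e-12 * max(1, best$gev))
        best <- run
    }
  })
  perMap <- vapply(seq_len(k), function(j) {
    idx <- best$labels == j
    sum((g[idx] * best$corr[idx])^2) / denom
  }, numeric(1))
  list(templates = TemplateSet(best$A, gevTotal = best$gev,
                               provenance = "modified-kmeans"),
       labels = best$labels, corr = best$corr,
       gev = list(perMap = perMap, total = best$gev),
       gevTrace = best$trace, iterations = best$it)
}

#' Global explained variance of a labeling
#'
#' `GEV_k = sum_{t: label=k} (gfp_t * corr_t)^2 / sum_t gfp_t^2`, where
#' `corr_t` is the absolute spatial correlation between map `t` and its
#' assigned template; the denominator runs over all segmented samples.
#'
#' @param x M x channels matrix of observed topographies.
#' @param templates A [TemplateSet-class] or K x channels matrix.
#' @param labels Integer template assignment per row of `x` (NA rows are
#'   excluded from the numerator but kept in the denominator). If missing,
#'   maps are backfit by maximum absolute correlation.
#' @return List with `perMap` (length K) and `total`.
#' @export
gev <- function(x, templates, labels = NULL) {
  A <- if (is(templates, "TemplateSet")) maps(templates) else
    normalizeMaps(as.matrix(templates))
  x <- as.matrix(x)
  Xc <- x - rowMeans(x)
  g <- sqrt(rowMeans(Xc^2))
  denom <- sum(g^2)
  if (denom <= 0) stop("zero total GFP: GEV undefined")
  cc <- .absCorrMatrix(Xc, A)
  if (is.null(labels)) labels <- max.col(cc, ties.method = "first")
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels length must match map count")
  ok <- !is.na(labels)
  corr <- rep(NA_real_, nrow(x))
  corr[ok] <- cc[cbind(which(ok), labels[ok])]
  perMap <- vapply(seq_len(nrow(A)), function(j) {
    idx <- ok & labels == j
    if (!any(idx)) return(0)
    sum((g[idx] * corr[idx])^2) / denom
  }, numeric(1))
  list(perMap = perMap, total = sum(perMap))
}
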