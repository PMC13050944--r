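## Cluster-validity criteria on the polarity-invariant distance
## d = sqrt(1 - corr^2), and the meta-criterion (median of per-criterion
## optimal K, ties to the smaller K).

.polarityDistance <- function(X) {
  Xn <- normalizeMaps(X)
  cc <- abs(tcrossprod(Xn))
  cc[cc > 1] <- 1
  d <- sqrt(1 - cc^2)
  diag(d) <- 0
  d
}

.lowerMedian <- function(v) {
  v <- sort(unname(v))
  v[ceiling(length(v) / 2)]
}

#' Seven-criterion clustering-quality battery and meta-criterion
#'
#' Evaluates fits over a range of cluster numbers with seven independent
#' validity criteria adapted to the polarity-invariant topographic distance
#' `d = sqrt(1 - corr^2)`: Silhouette (max), Davies-Bouldin (min),
#' Calinski-Harabasz (max), Dunn index (max), point-biserial correlation
#' (max), Krzanowski-Lai (max, interior K only) and a cross-validation
#' criterion (predictive residual variance, min). Each criterion nominates
#' an optimal K; the meta-criterion is the median of those optima with ties
#' broken toward the smaller K.
#'
#' @param fitsByK Named list of [modifiedKmeans()] fits, one per K; names
#'   are the K values.
#' @param x The M x channels matrix the fits were computed on.
#' @param criteria Character vector selecting which of the seven criteria to
#'   use (all by default; substitutable by name).
#' @return An object of class `metaCriterion`: list with `optima` (named
#'   integer vector, one optimal K per criterion), `metaK`, `values`
#'   (criterion x K matrix of raw criterion values), `searched` (K values).
#' @export
validityCriteria <- function(fitsByK, x,
                             criteria = c("silhouette", "daviesBouldin",
                                          "calinskiHarabasz", "dunn",
                                          "pointBiserial", "krzanowskiLai",
                                          "crossValidation")) {
  Ks <- as.integer(names(fitsByK))
  if (length(Ks) < 3L) stop("K range must span at least 3 values")
  if (any(is.na(Ks)) || is.unsorted(Ks)) stop("fitsByK must be named by increasing K")
  x <- as.matrix(x)
  M <- nrow(x); C <- ncol(x)
  Xc <- x - rowMeans(x)
  # degenerate fits (empty cluster) are excluded from the search
  degenerate <- vapply(seq_along(Ks), function(i) {
    length(unique(fitsByK[[i]]$labels)) < Ks[i]
  }, logical(1))
  if (any(degenerate)) {
    message("excluding degenerate fit(s) at K = ",
            paste(Ks[degenerate], collapse = ", "))
    fitsByK <- fitsByK[!degenerate]; Ks <- Ks[!degenerate]
    if (length(Ks) < 3L) stop("fewer than 3 non-degenerate fits remain")
  }
  D <- .polarityDistance(x)
  known <- c("silhouette", "daviesBouldin", "calinskiHarabasz", "dunn",
             "pointBiserial", "krzanowskiLai", "crossValidation")
  criteria <- match.arg(criteria, known, several.ok = TRUE)

  # within-cluster dispersion per K (shared by CH / KL / CV)
  W <- vapply(fitsByK, function(f) sum(1 - f$corr^2), numeric(1))
  totCorr <- .absCorrMatrix(Xc, matrix(.dominantMap(Xc), nrow = 1))
  Wtot <- sum(1 - totCorr^2)

  vals <- matrix(NA_real_, length(criteria), length(Ks),
                 dimnames = list(criteria, Ks))
  # pairwise-distance bookkeeping shared across K
  pairI <- rep(seq_len(M - 1), times = (M - 1):1)
  pairJ <- sequence((M - 1):1) + pairI
  dUp <- D[cbind(pairI, pairJ)]
  sdUp <- sd(dUp)
  for (i in seq_along(Ks)) {
    f <- fitsByK[[i]]; K <- Ks[i]; lab <- f$labels
    sameUp <- lab[pairI] == lab[pairJ]
    if ("silhouette" %in% criteria)
      vals["silhouette", i] <- .silhouetteMean(D, lab, K)
    if ("daviesBouldin" %in% criteria)
      vals["daviesBouldin", i] <- .daviesBouldin(Xc, f, K)
    if ("calinskiHarabasz" %in% criteria)
      vals["calinskiHarabasz", i] <-
        if (K > 1 && M > K) ((Wtot - W[i]) / (K - 1)) / (W[i] / (M - K)) else NA
    if ("dunn" %in% criteria) {
      between <- min(dUp[!sameUp])
      diam <- if (any(sameUp)) max(dUp[sameUp]) else 0
      vals["dunn", i] <- if (diam > 0) between / diam else NA
    }
    if ("pointBiserial" %in% criteria) {
      nw <- sum(sameUp)
      pw <- nw / length(dUp); pb <- 1 - pw
      vals["pointBiserial", i] <-
        if (sdUp > 0 && nw > 0 && nw < length(dUp))
          (mean(dUp[!sameUp]) - mean(dUp[sameUp])) * sqrt(pw * pb) / sdUp
        else NA
    }
    if ("crossValidation" %in% criteria) {
      # predictive residual variance (noise estimate penalized by K)
      sigma2 <- sum(rowSums(Xc^2) -
                      (rowSums(Xc * maps(f$templates)[lab, , drop = FALSE]))^2) /
        (M * (C - 1))
      vals["crossValidation", i] <-
        if (C - 1 - K > 0) sigma2 * ((C - 1) / (C - 1 - K))^2 else NA
    }
  }
  if ("krzanowskiLai" %in% criteria && length(Ks) >= 3) {
    p <- C - 1
    diffK <- function(i) (Ks[i - 1])^(2 / p) * W[i - 1] - (Ks[i])^(2 / p) * W[i]
    for (i in 2:(length(Ks) - 1)) {
      d1 <- diffK(i); d2 <- diffK(i + 1)
      vals["krzanowskiLai", i] <- if (abs(d2) > 0) abs(d1 / d2) else NA
    }
  }

  direction <- c(silhouette = 1, daviesBouldin = -1, calinskiHarabasz = 1,
                 dunn = 1, pointBiserial = 1, krzanowskiLai = 1,
                 crossValidation = -1)
  optima <- vapply(criteria, function(cr) {
    v <- vals[cr, ] * direction[[cr]]
    if (all(is.na(v))) return(NA_integer_)
    Ks[which.max(v)]        # which.max takes the first (smaller K) on ties
  }, integer(1))
  optima <- optima[!is.na(optima)]
  if (!length(optima)) stop("no criterion produced an optimum")
  structure(list(optima = optima, metaK = .lowerMedian(optima),
                 values = vals, searched = Ks),
            class = "metaCriterion")
}

.silhouetteMean <- function(D, lab, K) {
  if (K < 2) return(NA_real_)
  M <- nrow(D)
  s <- numeric(M)
  sizes <- tabulate(lab, K)
  # mean distance from each point to each cluster (D is symmetric)
  agg <- rowsum(D, lab)                       # K x M sums
  for (i in seq_len(M)) {
    k <- lab[i]
    if (sizes[k] <= 1) { s[i] <- 0; next }
    a <- agg[k, i] / (sizes[k] - 1)
    b <- min(agg[-k, i] / sizes[-k])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

.daviesBouldin <- function(Xc, fit, K) {
  if (K < 2) return(NA_real_)
  A <- maps(fit$templates)
  scatter <- vapply(seq_len(K), function(j) {
    idx <- fit$labels == j
    mean(sqrt(pmax(0, 1 - fit$corr[idx]^2)))
  }, numeric(1))
  cc <- abs(tcrossprod(A)); cc[cc > 1] <- 1
  dAB <- sqrt(1 - cc^2)
  r <- vapply(seq_len(K), function(j) {
    others <- setdiff(seq_len(K), j)
    max((scatter[j] + scatter[others]) / pmax(dAB[j, others], 1e-12))
  }, numeric(1))
  mean(r)
}

#' @export
print.metaCriterion <- function(x, ...) {
  cat("Meta-criterion over K in {", paste(x$searched, collapse = ", "), "}\n")
  cat("  per-criterion optima:\n")
  for (nm in names(x$optima))
    cat(sprintf("    %-18s K = %d\n", nm, x$optima[[nm]]))
  cat(sprintf("  meta K (lower median): %d\n", x$metaK))
  invisible(x)
}
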