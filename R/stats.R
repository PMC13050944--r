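## Nonparametric load-effect statistics: Friedman rank test with tie
## correction, Dunn's multiple-comparison post-hoc, and Pearson correlation.

#' Friedman rank test for repeated measures
#'
#' Ranks each subject's values across conditions (mid-ranks for ties), and
#' computes the Friedman chi-square statistic with the standard tie
#' correction. The p-value uses the chi-square approximation with
#' `df = k - 1`; a permutation option (within-subject relabeling, complete
#' enumeration when feasible) is available for small samples.
#'
#' @param x subjects x conditions numeric matrix (no missing cells).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param nPerm Monte-Carlo permutations when complete enumeration of the
#'   `factorial(k)^n` within-subject relabelings is infeasible.
#' @param seed Seed for Monte-Carlo permutation.
#' @return A `friedmanResult` list: `chi2`, `df`, `p`, `meanRanks`, `n`,
#'   `k`, `method`.
#' @export
friedmanTest <- function(x, method = c("chisq", "permutation"),
                         nPerm = 10000, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("missing or non-finite cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  stat <- function(m) {
    r <- t(apply(m, 1, rank))
    R <- colSums(r)
    ties <- sum(apply(m, 1, function(row) {
      t <- table(row); sum(t^3 - t)
    }))
    corr <- 1 - ties / (n * k * (k^2 - 1))
    if (corr <= 0) return(list(chi2 = 0, R = R))
    chi2 <- (12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)) / corr
    list(chi2 = max(chi2, 0), R = R)
  }
  obs <- stat(x)
  p <- pchisq(obs$chi2, df = k - 1, lower.tail = FALSE)
  if (method == "permutation") {
    total <- factorial(k)^n
    perms <- .permutationsOf(k)
    if (total <= 1e5) {
      idx <- rep(1L, n); count <- 0L; ge <- 0L
      repeat {
        m <- x
        for (i in seq_len(n)) m[i, ] <- x[i, perms[idx[i], ]]
        if (stat(m)$chi2 >= obs$chi2 - 1e-12) ge <- ge + 1L
        count <- count + 1L
        j <- 1L
        repeat {
          idx[j] <- idx[j] + 1L
          if (idx[j] <= nrow(perms)) break
          idx[j] <- 1L; j <- j + 1L
          if (j > n) break
        }
        if (j > n) break
      }
      p <- ge / count
    } else {
      set.seed(as.integer(seed))
      ge <- 0L
      for (b in seq_len(nPerm)) {
        m <- t(apply(x, 1, sample))
        if (stat(m)$chi2 >= obs$chi2 - 1e-12) ge <- ge + 1L
      }
      p <- (ge + 1) / (nPerm + 1)
    }
  }
  structure(list(chi2 = obs$chi2, df = k - 1, p = p,
                 meanRanks = obs$R / n, n = n, k = k, method = method),
            class = "friedmanResult")
}

.permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutationsOf(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (pos in seq_len(k)) for (i in seq_len(nrow(sub))) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], k, after = pos - 1L)
  }
  out
}

#' @export
print.friedmanResult <- function(x, ...) {
  cat(sprintf("Friedman test: chi2(%d) = %.4g, p = %.4g (%s)\n",
              x$df, x$chi2, x$p, x$method))
  cat("  mean ranks:", paste(sprintf("%.2f", x$meanRanks), collapse = ", "), "\n")
  invisible(x)
}

#' Dunn's post-hoc comparisons after a Friedman test
#'
#' For every condition pair, `z = (Rbar_i - Rbar_j) / sqrt(k(k+1)/(6n))`
#' with two-sided normal p-values and family-wise adjustment over the
#' compared pairs (all pairs by default, or each condition against a
#' baseline column).
#'
#' @param x subjects x conditions matrix.
#' @param alpha Family-wise significance level (default 0.05).
#' @param adjust Adjustment method for [stats::p.adjust()] (default
#'   "bonferroni").
#' @param control Optional baseline condition index; when given, only
#'   pairs against it are tested.
#' @return A `dunnResult` data.frame: i, j, z, p, pAdjusted, significant.
#' @export
dunnPosthoc <- function(x, alpha = 0.05, adjust = "bonferroni",
                        control = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("missing or non-finite cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  r <- t(apply(x, 1, rank))
  Rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- if (is.null(control)) {
    which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  } else {
    cbind(row = setdiff(seq_len(k), control), col = control)
  }
  z <- (Rbar[pairs[, 1]] - Rbar[pairs[, 2]]) / se
  p <- 2 * stats::pnorm(-abs(z))
  pAdj <- p.adjust(p, method = adjust)
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], z = z, p = p,
                    pAdjusted = pAdj, significant = pAdj < alpha)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("dunnResult", "data.frame")
  out
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation and the usual t-based two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return A `correlationResult` list: `r`, `p`, `n`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlationResult")
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, p = %.4g (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}
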