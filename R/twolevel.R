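## Two-level microstate procedure: within-subject clustering of GFP-peak
## topographies -> within-subject backfitting -> across-subject clustering of
## the pooled subject templates -> backfitting the final maps per load
## condition, yielding time frames and GEV per subject x condition x map.

#' Collect GFP-peak topographies from an EpochSet
#'
#' Scans every requested trial, computes the per-sample GFP, locates its
#' local maxima and returns the corresponding scalp maps as rows.
#'
#' @param epochs An [EpochSet-class].
#' @param subjects,conditions Integer indices to restrict to (default all).
#' @param peaksOnly If `FALSE`, every sample is returned instead of GFP
#'   peaks only.
#' @return List with `maps` (M x channels), `gfp` (length M), `info`
#'   (data.frame: subject, condition, trial, sample).
#' @export
gfpPeakMaps <- function(epochs, subjects = NULL, conditions = NULL,
                        peaksOnly = TRUE) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  if (is.null(subjects)) subjects <- seq_len(d[1])
  if (is.null(conditions)) conditions <- seq_len(d[2])
  mapsL <- list(); gfpL <- list(); infoL <- list(); idx <- 0L
  for (s in subjects) for (c in conditions) for (tr in seq_len(d[3])) {
    m <- trialMatrix(epochs, s, c, tr)
    g <- gfp(m)
    pk <- if (peaksOnly) findGfpPeaks(g) else seq_along(g)
    if (!length(pk)) next
    idx <- idx + 1L
    mapsL[[idx]] <- t(m[, pk, drop = FALSE])
    gfpL[[idx]] <- g[pk]
    infoL[[idx]] <- data.frame(subject = s, condition = c, trial = tr,
                               sample = pk)
  }
  if (!idx) stop("no GFP peaks found in the requested epochs")
  list(maps = do.call(rbind, mapsL), gfp = unlist(gfpL),
       info = do.call(rbind, infoL))
}

#' Within-subject template maps via meta-criterion model selection
#'
#' For every subject, pools GFP-peak topographies over all conditions and
#' trials, fits [modifiedKmeans()] for each K in `kRange`, and selects the
#' subject's number of maps by the seven-criterion meta-criterion.
#'
#' @param epochs An [EpochSet-class].
#' @param kRange Integer vector of candidate cluster numbers (>= 3 values).
#' @param seed Integer seed; per-subject and per-K sub-seeds are derived
#'   from it deterministically.
#' @param nRestarts Restarts per k-means fit.
#' @param criteria Criterion names passed to [validityCriteria()].
#' @return List of per-subject results, each with `templates`
#'   ([TemplateSet-class] at the meta-criterion K), `meta`
#'   (`metaCriterion` object), `fit` (the winning [modifiedKmeans()] fit)
#'   and `peaks` (the pooled GFP-peak set).
#' @export
withinSubjectTemplates <- function(epochs, kRange = 2:10, seed,
                                   nRestarts = 20L,
                                   criteria = eval(formals(validityCriteria)$criteria)) {
  stopifnot(is(epochs, "EpochSet"))
  if (missing(seed)) stop("seed is required")
  kRange <- sort(unique(as.integer(kRange)))
  out <- vector("list", nSubjects(epochs))
  for (s in seq_len(nSubjects(epochs))) {
    pk <- gfpPeakMaps(epochs, subjects = s)
    if (nrow(pk$maps) < max(kRange))
      stop(sprintf("subject %d has only %d GFP peaks (< max K = %d)",
                   s, nrow(pk$maps), max(kRange)))
    fits <- lapply(kRange, function(K)
      modifiedKmeans(pk$maps, K, nRestarts = nRestarts,
                     seed = .subSeed(seed, s, K)))
    names(fits) <- kRange
    meta <- validityCriteria(fits, pk$maps, criteria = criteria)
    fit <- fits[[as.character(meta$metaK)]]
    tpl <- fit$templates
    tpl@provenance <- sprintf("within-subject (subject %d, meta K = %d)",
                              s, meta$metaK)
    out[[s]] <- list(templates = tpl, meta = meta, fit = fit, peaks = pk)
  }
  out
}

## deterministic sub-seed derivation (splittable-generator stand-in);
## kept below 2^31
.subSeed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (p in parts) h <- (h * 7919 + (p %% 104729) + 13) %% 2147483629
  as.integer(h)
}

#' Backfit a template set to epochs
#'
#' Labels each GFP-peak sample (default) or every sample by the template
#' with the highest absolute spatial correlation; polarity is ignored.
#'
#' @param templates A [TemplateSet-class].
#' @param epochs An [EpochSet-class] (optionally restricted via `subjects`,
#'   `conditions`) or a plain M x channels matrix of maps.
#' @param subjects,conditions Restriction indices when `epochs` is an
#'   EpochSet.
#' @param peaksOnly Backfit GFP peaks only (default) or all samples.
#' @param minCorr Optional rejection gate: samples with winning |corr| below
#'   it are left unassigned (default 0 = off).
#' @return A [Segmentation-class].
#' @export
backfit <- function(templates, epochs, subjects = NULL, conditions = NULL,
                    peaksOnly = TRUE, minCorr = 0) {
  stopifnot(is(templates, "TemplateSet"))
  if (is(epochs, "EpochSet")) {
    pk <- gfpPeakMaps(epochs, subjects, conditions, peaksOnly = peaksOnly)
    X <- pk$maps; g <- pk$gfp; info <- pk$info
  } else {
    X <- as.matrix(epochs)
    g <- apply(X, 1, gfp)
    info <- NULL
  }
  if (ncol(X) != nChannels(templates))
    stop("channel counts of templates and data differ")
  cc <- .absCorrMatrix(X - rowMeans(X), maps(templates))
  labels <- max.col(cc, ties.method = "first")
  corr <- cc[cbind(seq_len(nrow(X)), labels)]
  if (minCorr > 0) {
    drop <- corr < minCorr
    labels[drop] <- NA_integer_
    corr[drop] <- NA_real_
  }
  Segmentation(labels, corr, g, sampleInfo = info)
}

#' Across-subject template maps (second clustering level)
#'
#' Pools all subject-level template maps as observations, clusters them over
#' `kRange` and selects the final K by the meta-criterion. With a single
#' subject the pooling is degenerate and that subject's template set is
#' returned unchanged.
#'
#' @param subjectTemplates List of [TemplateSet-class] objects (or the
#'   result list of [withinSubjectTemplates()]).
#' @param kRange Candidate K values.
#' @param seed Integer seed.
#' @param nRestarts Restarts per fit.
#' @param criteria Criterion names for [validityCriteria()].
#' @return List with `templates` (final [TemplateSet-class]), `meta`, `fit`,
#'   `pooled` (the pooled map matrix).
#' @export
acrossSubjectTemplates <- function(subjectTemplates, kRange = 2:10, seed,
                                   nRestarts = 20L,
                                   criteria = eval(formals(validityCriteria)$criteria)) {
  if (missing(seed)) stop("seed is required")
  tpls <- lapply(subjectTemplates, function(x)
    if (is(x, "TemplateSet")) x else x$templates)
  if (length(tpls) == 1L)
    return(list(templates = tpls[[1]], meta = NULL, fit = NULL,
                pooled = maps(tpls[[1]])))
  pooled <- do.call(rbind, lapply(tpls, maps))
  kRange <- sort(unique(as.integer(kRange)))
  kRange <- kRange[kRange <= nrow(pooled)]
  if (length(kRange) < 3L)
    stop("too few pooled subject maps for the requested K range")
  fits <- lapply(kRange, function(K)
    modifiedKmeans(pooled, K, nRestarts = nRestarts,
                   seed = .subSeed(seed, 0L, K)))
  names(fits) <- kRange
  meta <- validityCriteria(fits, pooled, criteria = criteria)
  fit <- fits[[as.character(meta$metaK)]]
  tpl <- fit$templates
  tpl@provenance <- sprintf("across-subject (meta K = %d, %d subjects)",
                            meta$metaK, length(tpls))
  list(templates = tpl, meta = meta, fit = fit, pooled = pooled)
}

#' Per-condition microstate parameters from final templates
#'
#' Backfits the final maps to every subject x condition cell and accumulates
#' the number of assigned time frames and the GEV per map. GEV is
#' normalized within each subject x condition cell; cells in which a map is
#' never assigned get `timeFrames = 0` and `gev = 0`.
#'
#' @param final A [TemplateSet-class] (across-subject maps).
#' @param epochs An [EpochSet-class].
#' @param peaksOnly Backfit GFP peaks only (default) or all samples.
#' @param minCorr Optional assignment gate (see [backfit()]).
#' @return A `microstateStats` data.frame: subject, condition, map,
#'   timeFrames, gev, occurrence (timeFrames / segmented samples in the
#'   cell).
#' @export
conditionStats <- function(final, epochs, peaksOnly = TRUE, minCorr = 0) {
  stopifnot(is(final, "TemplateSet"), is(epochs, "EpochSet"))
  K <- nMaps(final)
  rows <- list(); r <- 0L
  for (s in seq_len(nSubjects(epochs))) for (c in seq_len(nConditions(epochs))) {
    seg <- backfit(final, epochs, subjects = s, conditions = c,
                   peaksOnly = peaksOnly, minCorr = minCorr)
    nTot <- length(seg@labels)
    denom <- sum(seg@gfp^2)
    for (k in seq_len(K)) {
      idx <- !is.na(seg@labels) & seg@labels == k
      tf <- sum(idx)
      gv <- if (tf && denom > 0)
        sum((seg@gfp[idx] * seg@corr[idx])^2) / denom else 0
      r <- r + 1L
      rows[[r]] <- data.frame(subject = s, condition = c, map = k,
                              timeFrames = tf, gev = gv,
                              occurrence = tf / nTot)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("microstateStats", "data.frame")
  out
}

#' Greedy one-to-one matching of two template sets by |spatial correlation|
#'
#' Repeatedly pairs the globally best-correlated (template, reference)
#' couple until one side is exhausted; used to give recovered maps a stable
#' numbering against a reference set (e.g. planted ground-truth maps).
#'
#' @param x,reference [TemplateSet-class] objects or map matrices.
#' @return data.frame with columns `map` (row of `x`), `reference` (matched
#'   row of `reference`), `corr` (absolute spatial correlation).
#' @export
matchMaps <- function(x, reference) {
  A <- if (is(x, "TemplateSet")) maps(x) else normalizeMaps(as.matrix(x))
  B <- if (is(reference, "TemplateSet")) maps(reference) else
    normalizeMaps(as.matrix(reference))
  cc <- abs(tcrossprod(A, B))
  out <- data.frame(map = integer(0), reference = integer(0), corr = numeric(0))
  while (nrow(out) < min(nrow(A), nrow(B))) {
    w <- arrayInd(which.max(cc), dim(cc))
    out <- rbind(out, data.frame(map = w[1], reference = w[2],
                                 corr = cc[w[1], w[2]]))
    cc[w[1], ] <- -1
    cc[, w[2]] <- -1
  }
  out[order(out$map), , drop = FALSE]
}
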