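## Formats: plain-text `.ep` matrices (one sample per row), a minimal EDF
## reader/writer, onset lists, YAML pipeline configuration.

#' Write / read a plain-text `.ep` potential matrix
#'
#' The `.ep` dialect is a whitespace-separated numeric matrix with one
#' sample per row and one channel per column, values at 9 significant
#' digits (round-trip stable at that precision). `readEp()` returns the
#' conventional channels x samples orientation.
#'
#' @param x channels x samples numeric matrix.
#' @param path File path.
#' @return `writeEp` returns `path` invisibly; `readEp` returns a
#'   channels x samples matrix.
#' @export
writeEp <- function(x, path) {
  x <- .asChannelMatrix(x)
  lines <- apply(t(x), 1, function(row)
    paste(sprintf("%.9g", row), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeEp
#' @export
readEp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty .ep file: ", path)
  rows <- strsplit(trimws(lines), "[ \t]+")
  nc <- length(rows[[1]])
  for (i in seq_along(rows))
    if (length(rows[[i]]) != nc)
      stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                   path, i, length(rows[[i]]), nc))
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), ncol = nc,
              byrow = TRUE)
  if (any(is.na(m))) stop("non-numeric field in ", path)
  t(m)
}

#' Write an EpochSet to a directory of `.ep` files with a JSON sidecar
#'
#' One `.ep` matrix per trial (named `s<subject>_c<condition>_t<trial>.ep`)
#' plus `epochset.json` carrying montage labels, sampling rate, epoch
#' window, design counts and - for synthetic data - the planted template
#' maps and prevalences.
#'
#' @param epochs An [EpochSet-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEpochSetDir <- function(epochs, dir) {
  stopifnot(is(epochs, "EpochSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs@data)
  for (s in seq_len(d[1])) for (c in seq_len(d[2])) for (tr in seq_len(d[3]))
    writeEp(trialMatrix(epochs, s, c, tr),
            file.path(dir, sprintf("s%02d_c%02d_t%02d.ep", s, c, tr)))
  meta <- list(channelLabels = epochs@channelLabels, srate = epochs@srate,
               epochWindow = epochs@epochWindow,
               design = list(nSubjects = d[1], nConditions = d[2],
                             nTrials = d[3], nChannels = d[4],
                             nSamples = d[5]))
  if (length(epochs@truth)) {
    meta$truth <- list(plantedMaps = epochs@truth$plantedMaps,
                       prevalence = epochs@truth$prevalence,
                       seed = epochs@truth$seed)
  }
  jsonlite::write_json(meta, file.path(dir, "epochset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeEpochSetDir
#' @export
readEpochSetDir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochset.json"),
                              simplifyVector = TRUE)
  dn <- meta$design
  data <- array(0, dim = c(dn$nSubjects, dn$nConditions, dn$nTrials,
                           dn$nChannels, dn$nSamples))
  for (s in seq_len(dn$nSubjects)) for (c in seq_len(dn$nConditions))
    for (tr in seq_len(dn$nTrials))
      data[s, c, tr, , ] <-
        readEp(file.path(dir, sprintf("s%02d_c%02d_t%02d.ep", s, c, tr)))
  truth <- if (!is.null(meta$truth))
    list(plantedMaps = as.matrix(meta$truth$plantedMaps),
         prevalence = meta$truth$prevalence, seed = meta$truth$seed)
  else list()
  EpochSet(data, meta$channelLabels, meta$srate, meta$epochWindow,
           truth = truth)
}

#' Write / read a template set as `.ep` + JSON metadata
#'
#' The maps matrix is written with one map per row; the JSON sidecar holds
#' K, total GEV and provenance.
#'
#' @param x A [TemplateSet-class].
#' @param basePath Path without extension; `<basePath>.ep` and
#'   `<basePath>.json` are written.
#' @return `basePath` invisibly (`writeTemplateSet`); a
#'   [TemplateSet-class] (`readTemplateSet`).
#' @export
writeTemplateSet <- function(x, basePath) {
  stopifnot(is(x, "TemplateSet"))
  writeEp(t(maps(x)), paste0(basePath, ".ep"))
  jsonlite::write_json(list(K = nMaps(x), gevTotal = gevTotal(x),
                            provenance = x@provenance),
                       paste0(basePath, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(basePath)
}

#' @rdname writeTemplateSet
#' @export
readTemplateSet <- function(basePath) {
  m <- t(readEp(paste0(basePath, ".ep")))
  meta <- jsonlite::read_json(paste0(basePath, ".json"),
                              simplifyVector = TRUE)
  TemplateSet(m, gevTotal = meta$gevTotal, provenance = meta$provenance)
}

#' Export a Segmentation as tidy CSV
#'
#' Columns: (subject, condition, trial, sample when available), label,
#' corr, gfp.
#'
#' @param seg A [Segmentation-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSegmentationCsv <- function(seg, path) {
  stopifnot(is(seg, "Segmentation"))
  base <- data.frame(label = seg@labels, corr = seg@corr, gfp = seg@gfp)
  if (!is.null(seg@sampleInfo)) base <- cbind(seg@sampleInfo, base)
  write.csv(base, path, row.names = FALSE)
  invisible(path)
}

#' Read a one-integer-per-line onset list
#'
#' @param path Text file, one sample index per line; blank lines and `#`
#'   comments ignored.
#' @return Integer vector.
#' @export
readOnsets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  v <- suppressWarnings(as.integer(lines))
  if (any(is.na(v))) stop("non-integer onset entry in ", path)
  v
}

## ---- minimal EDF -------------------------------------------------------

.edfPad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too long: ", s)
  formatC(s, width = -width)
}

#' Minimal EDF writer / reader for continuous multichannel data
#'
#' Writes a single-record EDF file (record duration = total duration) with
#' 16-bit quantization scaled to the data range; reads standard
#' multi-record EDF with per-signal physical scaling. Intended for data
#' exchange of synthetic or preprocessed recordings, not as a full
#' implementation of the EDF+ specification.
#'
#' @param x channels x samples matrix.
#' @param srate Sampling rate.
#' @param path File path.
#' @param labels Channel labels (default Ch1..ChN).
#' @return `writeEdf` returns `path` invisibly; `readEdf` returns a list
#'   with `data` (channels x samples), `srate`, `labels`.
#' @export
writeEdf <- function(x, srate, path, labels = NULL) {
  x <- .asChannelMatrix(x)
  ns <- nrow(x); n <- ncol(x)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(ns))
  rng <- max(abs(x), 1e-6)
  physMax <- signif(rng * 1.0001, 6)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.edfPad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("premstates export", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(1, 8)
  wr(sprintf("%.6g", n / srate), 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", -physMax), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", physMax), 8)
  for (i in seq_len(ns)) wr(-32767, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round((x + physMax) / (2 * physMax) * 65534 - 32767)
  for (i in seq_len(ns))
    writeBin(as.integer(dig[i, ]), con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname writeEdf
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  out <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(nRec)) for (i in seq_len(ns)) {
    raw <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
    out[[i]] <- c(out[[i]], physMin[i] + (raw - digMin[i]) *
                    (physMax[i] - physMin[i]) / (digMax[i] - digMin[i]))
  }
  data <- do.call(rbind, out)
  rownames(data) <- labels
  list(data = data, srate = spr[1] / recDur, labels = labels)
}

## ---- pipeline configuration -------------------------------------------

#' Default end-to-end pipeline configuration
#'
#' All tunables of the synthetic pipeline with study-like defaults: 10
#' subjects x 5 conditions x 10 trials of 500 ms pre-movement epochs at
#' 250 Hz on the 32-channel montage, 8 planted maps at SNR 2, K searched
#' over 2..10 by the meta-criterion, Friedman/Dunn over the four load
#' conditions at alpha 0.05, and a ~500-voxel source grid with sign-flip
#' permutation correction.
#'
#' @return Named list of class `pipelineConfig`.
#' @export
defaultPipelineConfig <- function() {
  structure(list(
    seed = 1L,
    nSubjects = 10L, nConditions = 5L, nTrials = 10L,
    nChannels = 32L, nSamples = 125L, srate = 250,
    K = 8L, snr = 2, segmentDwell = 12, mapJitter = 0.05,
    prevalenceRange = c(0.25, 0.05), effectMap = 2L,
    kMin = 2L, kMax = 10L, nRestarts = 20L,
    peaksOnly = TRUE, minCorr = 0,
    loadConditions = c(2L, 3L, 4L, 5L),
    alphaLevel = 0.05, dunnAdjust = "bonferroni",
    sources = TRUE, gridSpacingMm = 12, gridRadiusMm = 60,
    nPermutations = 5000L, sourceAlpha = "auto",
    figures = TRUE
  ), class = "pipelineConfig")
}

#' Read and validate a YAML pipeline configuration
#'
#' Starts from [defaultPipelineConfig()] and overrides the keys present in
#' the file; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A validated `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg A configuration list.
#' @export
validatePipelineConfig <- function(cfg) {
  num1 <- function(k) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config key '", k, "' must be a positive number")
  }
  for (k in c("nSubjects", "nConditions", "nTrials", "nChannels",
              "nSamples", "srate", "K", "snr", "segmentDwell",
              "nRestarts", "alphaLevel", "gridSpacingMm", "gridRadiusMm",
              "nPermutations")) num1(k)
  if (cfg$kMin < 2L || cfg$kMax <= cfg$kMin + 1L)
    stop("need kMin >= 2 and kMax >= kMin + 2 (meta-criterion needs >= 3 K values)")
  if (cfg$K > cfg$nChannels) stop("K cannot exceed the channel count")
  if (any(cfg$loadConditions > cfg$nConditions))
    stop("loadConditions outside 1..nConditions")
  class(cfg) <- "pipelineConfig"
  cfg
}
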