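## Central S4 containers: EpochSet (epoched multi-subject EEG), TemplateSet
## (microstate template maps), Segmentation (per-sample labeling), LeadField
## (forward model). Lighter results (tables, test results) are plain
## data.frames / lists with a class attribute.

setClassUnion("listOrNULL", c("list", "NULL"))

#' EpochSet: epoched multi-subject, multi-condition EEG
#'
#' Potentials are stored as a 5-dimensional array indexed
#' subject x condition x trial x channel x sample (microvolts). The epoch
#' window is expressed in milliseconds relative to movement onset; for
#' pre-movement sets the window must end at or before 0 ms.
#'
#' @slot data 5-D numeric array (subject, condition, trial, channel, sample).
#' @slot channelLabels Ordered channel names; length equals dim 4 of `data`.
#' @slot srate Sampling rate, samples/s.
#' @slot epochWindow Numeric length-2, (start_ms, end_ms) relative to onset.
#' @slot truth Optional list carrying the generator's ground truth (planted
#'   maps, realized per-sample segment labels, prevalences); empty for real
#'   data.
#' @export
setClass("EpochSet",
  representation(data = "array", channelLabels = "character",
                 srate = "numeric", epochWindow = "numeric",
                 truth = "listOrNULL"),
  prototype(truth = list()))

setValidity("EpochSet", function(object) {
  d <- object@data
  if (length(dim(d)) != 5L)
    return("data must be a 5-D array (subject, condition, trial, channel, sample)")
  if (dim(d)[4] != length(object@channelLabels))
    return("channel count does not match channelLabels")
  if (any(!is.finite(d)))
    return("data contains non-finite samples")
  if (length(object@srate) != 1L || object@srate <= 0)
    return("srate must be a positive scalar")
  if (length(object@epochWindow) != 2L || diff(object@epochWindow) <= 0)
    return("epochWindow must be (start_ms, end_ms) with start < end")
  if (object@epochWindow[2] > 0)
    return("epochWindow must end at or before 0 ms for pre-movement epochs")
  TRUE
})

#' Construct an EpochSet
#'
#' @param data 5-D array (subject, condition, trial, channel, sample), microvolts.
#' @param channelLabels Channel names matching dim 4.
#' @param srate Sampling rate (samples/s).
#' @param epochWindow (start_ms, end_ms) relative to movement onset;
#'   defaults to the 500 ms pre-movement window.
#' @param truth Optional ground-truth list from the generator.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, channelLabels, srate, epochWindow = c(-500, 0),
                     truth = list()) {
  new("EpochSet", data = data, channelLabels = channelLabels,
      srate = srate, epochWindow = as.numeric(epochWindow), truth = truth)
}

#' TemplateSet: an ordered set of K microstate template maps
#'
#' Rows are average-referenced, L2-normalized topographies; polarity is a
#' non-identifying degree of freedom (a map and its negation denote the same
#' state).
#'
#' @slot maps K x channels numeric matrix, one normalized map per row.
#' @slot gevTotal Total global explained variance attained by the fit (0-1),
#'   NA when not applicable.
#' @slot provenance Which clustering level produced the set
#'   (e.g. "within-subject", "across-subject").
#' @export
setClass("TemplateSet",
  representation(maps = "matrix", gevTotal = "numeric", provenance = "character"))

setValidity("TemplateSet", function(object) {
  m <- object@maps
  if (nrow(m) < 1L || nrow(m) > ncol(m))
    return("need 1 <= K <= channel count")
  if (any(abs(rowMeans(m)) > 1e-8))
    return("maps must be average-referenced (zero channel mean)")
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-8))
    return("maps must have unit L2 norm")
  g <- object@gevTotal
  if (length(g) != 1L || (!is.na(g) && (g < 0 || g > 1)))
    return("gevTotal must be a scalar in [0, 1] or NA")
  TRUE
})

#' Construct a TemplateSet
#'
#' Maps are centered and renormalized on construction so that the polarity
#' and scale conventions hold exactly.
#'
#' @param maps K x channels matrix of topographies (one map per row).
#' @param gevTotal Total GEV of the producing fit (default NA).
#' @param provenance Free-text origin tag.
#' @return A [TemplateSet-class] object.
#' @export
TemplateSet <- function(maps, gevTotal = NA_real_, provenance = "user") {
  maps <- normalizeMaps(maps)
  new("TemplateSet", maps = maps, gevTotal = as.numeric(gevTotal),
      provenance = provenance)
}

#' Segmentation: per-timepoint template assignment
#'
#' @slot labels Integer template index per segmented sample (NA = unassigned).
#' @slot corr Absolute spatial correlation with the winning template, in [0,1].
#' @slot gfp Global field power at each segmented sample.
#' @slot sampleInfo Optional data.frame locating each segmented sample
#'   (subject, condition, trial, sample columns).
#' @export
setClass("Segmentation",
  representation(labels = "integer", corr = "numeric", gfp = "numeric",
                 sampleInfo = "listOrNULL"))

setValidity("Segmentation", function(object) {
  n <- length(object@labels)
  if (length(object@corr) != n || length(object@gfp) != n)
    return("labels, corr and gfp must have equal length")
  ok <- !is.na(object@corr)
  if (any(object@corr[ok] < -1e-12 | object@corr[ok] > 1 + 1e-12))
    return("corr must lie in [0, 1]")
  if (any(object@gfp < 0))
    return("gfp must be non-negative")
  if (any(is.na(object@labels) & ok))
    return("label must be defined wherever corr is")
  TRUE
})

Segmentation <- function(labels, corr, gfp, sampleInfo = NULL) {
  new("Segmentation", labels = as.integer(labels), corr = as.numeric(corr),
      gfp = as.numeric(gfp), sampleInfo = sampleInfo)
}

#' LeadField: spherical-head forward model on a voxel grid
#'
#' @slot gain channels x (3 * voxels) matrix; columns are grouped by voxel
#'   (x, y, z dipole orientations). Rows are average-referenced.
#' @slot voxels voxels x 3 matrix of grid positions (mm).
#' @slot radii Outward radii (mm) of the three concentric shells
#'   (brain, skull, scalp).
#' @slot conductivities Conductivities (S/m) of the three shells.
#' @slot channelLabels Electrode names for the gain rows.
#' @export
setClass("LeadField",
  representation(gain = "matrix", voxels = "matrix", radii = "numeric",
                 conductivities = "numeric", channelLabels = "character"))

setValidity("LeadField", function(object) {
  if (ncol(object@gain) != 3L * nrow(object@voxels))
    return("gain must have 3 columns per voxel")
  if (nrow(object@gain) != length(object@channelLabels))
    return("gain rows must match channelLabels")
  if (any(!is.finite(object@gain)))
    return("gain must be finite")
  if (max(abs(colMeans(object@gain))) > 1e-8)
    return("gain columns must be average-referenced")
  if (length(object@radii) != 3L || any(diff(object@radii) <= 0))
    return("radii must be three increasing shell radii")
  TRUE
})

#' SourceEstimate: standardized current density power per voxel
#'
#' @slot power Non-negative standardized power, one value per voxel.
#' @slot voxels voxels x 3 grid positions (mm).
#' @export
setClass("SourceEstimate",
  representation(power = "numeric", voxels = "matrix"))

setValidity("SourceEstimate", function(object) {
  if (length(object@power) != nrow(object@voxels))
    return("one power value per voxel required")
  if (any(!is.finite(object@power)) || any(object@power < -1e-12))
    return("power must be finite and non-negative")
  TRUE
})

## ---- generics and accessors -------------------------------------------

#' @rdname EpochSet-class
#' @param object,x An object.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EpochSet-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname EpochSet-class
#' @export
setGeneric("srate", function(x) standardGeneric("srate"))
#' @rdname EpochSet-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname TemplateSet-class
#' @export
setGeneric("maps", function(x) standardGeneric("maps"))
#' @rdname TemplateSet-class
#' @export
setGeneric("nMaps", function(x) standardGeneric("nMaps"))
#' @rdname TemplateSet-class
#' @export
setGeneric("gevTotal", function(x) standardGeneric("gevTotal"))

#' @rdname EpochSet-class
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[4])
#' @rdname EpochSet-class
#' @export
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[5])
#' @rdname EpochSet-class
#' @export
setMethod("srate", "EpochSet", function(x) x@srate)
#' @rdname EpochSet-class
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname EpochSet-class
#' @export
setMethod("dim", "EpochSet", function(x) dim(x@data))

#' Number of subjects / conditions / trials in an EpochSet
#' @param x An [EpochSet-class].
#' @return Integer count.
#' @export
nSubjects <- function(x) dim(x@data)[1]
#' @rdname nSubjects
#' @export
nConditions <- function(x) dim(x@data)[2]
#' @rdname nSubjects
#' @export
nTrials <- function(x) dim(x@data)[3]

#' Extract one trial's channels x samples matrix
#' @param x An [EpochSet-class].
#' @param subject,condition,trial Indices.
#' @return channels x samples numeric matrix.
#' @export
trialMatrix <- function(x, subject, condition, trial) {
  m <- x@data[subject, condition, trial, , ]
  dim(m) <- dim(x@data)[4:5]
  rownames(m) <- x@channelLabels
  m
}

#' @rdname TemplateSet-class
#' @param x A TemplateSet.
#' @export
setMethod("maps", "TemplateSet", function(x) x@maps)
#' @rdname TemplateSet-class
#' @export
setMethod("nMaps", "TemplateSet", function(x) nrow(x@maps))
#' @rdname TemplateSet-class
#' @export
setMethod("gevTotal", "TemplateSet", function(x) x@gevTotal)
#' @rdname TemplateSet-class
#' @export
setMethod("nChannels", "TemplateSet", function(x) ncol(x@maps))

#' @rdname LeadField-class
#' @param x A LeadField.
#' @export
setMethod("nChannels", "LeadField", function(x) nrow(x@gain))

#' Number of voxels in a lead field or source estimate
#' @param x A [LeadField-class] or [SourceEstimate-class].
#' @return Integer voxel count.
#' @export
nVoxels <- function(x) nrow(x@voxels)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d subject(s) x %d condition(s) x %d trial(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %d channels x %d samples @ %g Hz, window [%g, %g] ms\n",
              d[4], d[5], object@srate,
              object@epochWindow[1], object@epochWindow[2]))
  if (length(object@truth))
    cat("  carries generator ground truth (planted maps + labels)\n")
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d map(s) x %d channels (%s)\n",
              nrow(object@maps), ncol(object@maps), object@provenance))
  if (!is.na(object@gevTotal))
    cat(sprintf("  total GEV: %.4f\n", object@gevTotal))
})

setMethod("show", "Segmentation", function(object) {
  n <- length(object@labels)
  cat(sprintf("Segmentation: %d sample(s), %d template(s) used\n",
              n, length(unique(na.omit(object@labels)))))
  if (n)
    cat(sprintf("  mean |spatial corr|: %.4f\n", mean(object@corr, na.rm = TRUE)))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d voxels (3 orientations each)\n",
              nrow(object@gain), nrow(object@voxels)))
  cat(sprintf("  3-shell spherical model, radii %s mm\n",
              paste(signif(object@radii, 3), collapse = "/")))
})

setMethod("show", "SourceEstimate", function(object) {
  cat(sprintf("SourceEstimate: %d voxels, max standardized power %.4g\n",
              nrow(object@voxels), max(object@power)))
})
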