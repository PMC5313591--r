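#' @import methods
NULL

#' One free induction decay with its acquisition parameters
#'
#' `FidRecord` holds a single complex time-domain NMR signal together with
#' the acquisition parameters needed to transform it onto a chemical-shift
#' axis: the sampling (dwell) interval, spectrometer frequency, spectral
#' width, carrier offset and the digital-filter group delay.
#'
#' @slot signal complex vector, the FID (one complex point per dwell).
#' @slot dwellUs sampling interval in microseconds.
#' @slot sfoMHz spectrometer (observe) frequency in MHz.
#' @slot swPpm spectral width in ppm.
#' @slot o1Hz carrier offset in Hz; the carrier sits at `o1Hz / sfoMHz` ppm.
#' @slot groupDelay digital-filter delay in points (may be fractional).
#' @slot vendor `"bruker"`, `"varian"` or `"synthetic"`.
#' @slot sampleId sample identifier.
#' @export
setClass("FidRecord",
  representation(
    signal = "complex",
    dwellUs = "numeric",
    sfoMHz = "numeric",
    swPpm = "numeric",
    o1Hz = "numeric",
    groupDelay = "numeric",
    vendor = "character",
    sampleId = "character"
  ),
  prototype(groupDelay = 0, vendor = "synthetic", sampleId = "sample")
)

setValidity("FidRecord", function(object) {
  msg <- character()
  if (length(object@signal) < 2) msg <- c(msg, "signal must have at least 2 points")
  if (!(length(object@swPpm) == 1 && is.finite(object@swPpm) && object@swPpm > 0))
    msg <- c(msg, "swPpm must be a single positive number")
  if (!(length(object@sfoMHz) == 1 && is.finite(object@sfoMHz) && object@sfoMHz > 0))
    msg <- c(msg, "sfoMHz must be a single positive number")
  if (!(length(object@dwellUs) == 1 && object@dwellUs > 0))
    msg <- c(msg, "dwellUs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn FidRecord-class constructor.
#' @param signal,dwellUs,sfoMHz,swPpm,o1Hz,groupDelay,vendor,sampleId slot values.
#' @export
fidRecord <- function(signal, dwellUs, sfoMHz, swPpm, o1Hz = 0,
                      groupDelay = 0, vendor = "synthetic",
                      sampleId = "sample") {
  new("FidRecord", signal = as.complex(signal), dwellUs = dwellUs,
      sfoMHz = sfoMHz, swPpm = swPpm, o1Hz = o1Hz, groupDelay = groupDelay,
      vendor = vendor, sampleId = sampleId)
}

#' Spectral-axis specification for simulation
#'
#' Defines the grid a simulated spectrum (or FID) lives on: spectrometer
#' frequency, ppm limits and point count. The ppm axis is uniform and
#' descending with spacing `(ppmMax - ppmMin) / (points - 1)`, first point
#' at `ppmMax`. The carrier is placed at the centre of the window.
#'
#' @slot sfoMHz spectrometer frequency (MHz).
#' @slot ppmMin,ppmMax chemical-shift limits (ppm).
#' @slot points number of axis points.
#' @export
setClass("SpectralAxis",
  representation(sfoMHz = "numeric", ppmMin = "numeric",
                 ppmMax = "numeric", points = "integer")
)

setValidity("SpectralAxis", function(object) {
  msg <- character()
  if (object@sfoMHz <= 0) msg <- c(msg, "sfoMHz must be positive")
  if (object@ppmMin >= object@ppmMax) msg <- c(msg, "ppmMin must be < ppmMax")
  if (object@points < 8) msg <- c(msg, "points must be >= 8")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectralAxis-class constructor.
#' @param sfoMHz,ppmMin,ppmMax,points slot values.
#' @export
spectralAxis <- function(sfoMHz, ppmMin, ppmMax, points) {
  new("SpectralAxis", sfoMHz = sfoMHz, ppmMin = ppmMin, ppmMax = ppmMax,
      points = as.integer(points))
}

#' A closed chemical-shift interval
#'
#' Zones delimit the region a processing operation acts on. Intervals are
#' closed: an axis point at `ppm` belongs to the zone iff
#' `ppmMin <= ppm <= ppmMax`.
#'
#' @slot ppmMin,ppmMax interval limits in ppm, `ppmMin < ppmMax`.
#' @export
setClass("PpmZone", representation(ppmMin = "numeric", ppmMax = "numeric"))

setValidity("PpmZone", function(object) {
  if (!(length(object@ppmMin) == 1 && length(object@ppmMax) == 1 &&
        is.finite(object@ppmMin) && is.finite(object@ppmMax)))
    return("ppmMin and ppmMax must be single finite numbers")
  if (object@ppmMin >= object@ppmMax) return("ppmMin must be < ppmMax")
  TRUE
})

#' @describeIn PpmZone-class constructor.
#' @param ppmMin,ppmMax interval limits (ppm).
#' @export
ppmZone <- function(ppmMin, ppmMax) new("PpmZone", ppmMin = ppmMin, ppmMax = ppmMax)

#' A set of 1D NMR spectra on one shared ppm axis
#'
#' The central container: an N x P matrix of real intensities (spectra in
#' rows), one strictly decreasing ppm axis shared by all spectra, a sample
#' table carrying the experimental-factor levels that drive subset
#' operations, the solvent/contaminant zones excluded from bucketing, and
#' the provenance: the macro commands applied so far, replayable in batch.
#'
#' @slot intensities N x P numeric matrix, `rownames` are sample ids.
#' @slot ppm length-P strictly decreasing chemical-shift axis (ppm).
#' @slot sampleData data.frame with first column `sample_id` and one or
#'   more experimental-factor columns; exactly one row per spectrum.
#' @slot excluded k x 2 numeric matrix (columns `min`, `max`) of ppm zones
#'   excluded from bucketing.
#' @slot provenance character vector of macro-command lines.
#' @export
setClass("SpectrumSet",
  representation(
    intensities = "matrix",
    ppm = "numeric",
    sampleData = "data.frame",
    excluded = "matrix",
    provenance = "character"
  ),
  prototype(excluded = matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("min", "max"))),
            provenance = character(0))
)

setValidity("SpectrumSet", function(object) {
  msg <- character()
  n <- nrow(object@intensities); p <- ncol(object@intensities)
  if (length(object@ppm) != p)
    msg <- c(msg, "ppm axis length must equal ncol(intensities)")
  if (p >= 2 && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing")
  if (nrow(object@sampleData) != n)
    msg <- c(msg, "sampleData must have one row per spectrum")
  if (!"sample_id" %in% colnames(object@sampleData))
    msg <- c(msg, "sampleData must contain a sample_id column")
  else if (anyDuplicated(object@sampleData$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (ncol(object@excluded) != 2)
    msg <- c(msg, "excluded must have two columns (min, max)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectrumSet-class constructor.
#' @param intensities,ppm,sampleData,excluded,provenance slot values.
#' @export
spectrumSet <- function(intensities, ppm, sampleData,
                        excluded = NULL, provenance = character(0)) {
  if (is.null(excluded))
    excluded <- matrix(numeric(0), ncol = 2,
                       dimnames = list(NULL, c("min", "max")))
  sampleData$sample_id <- as.character(sampleData$sample_id)
  rownames(intensities) <- sampleData$sample_id
  new("SpectrumSet", intensities = intensities, ppm = as.numeric(ppm),
      sampleData = sampleData, excluded = excluded, provenance = provenance)
}

#' An ordered table of buckets
#'
#' Buckets are the ppm intervals whose integrals form the columns of the
#' data matrix. The table is kept in descending order of bucket centre and
#' buckets never overlap (closed-interval interiors are disjoint).
#'
#' @slot buckets data.frame with columns `label`, `ppm_min`, `ppm_max`.
#' @export
setClass("BucketTable", representation(buckets = "data.frame"))

setValidity("BucketTable", function(object) {
  b <- object@buckets
  need <- c("label", "ppm_min", "ppm_max")
  if (!all(need %in% colnames(b)))
    return("buckets must have columns label, ppm_min, ppm_max")
  if (nrow(b)) {
    if (any(b$ppm_min >= b$ppm_max)) return("every bucket needs ppm_min < ppm_max")
    ctr <- (b$ppm_min + b$ppm_max) / 2
    if (is.unsorted(rev(ctr), strictly = FALSE))
      return("buckets must be in descending order of centre ppm")
    if (nrow(b) > 1) {
      # descending order: next bucket must end at or below current start
      if (any(b$ppm_max[-1] > b$ppm_min[-nrow(b)] + 1e-12))
        return("buckets must not overlap")
    }
    if (anyDuplicated(b$label)) return("bucket labels must be unique")
  }
  TRUE
})

#' @describeIn BucketTable-class constructor; sorts descending by centre and
#'   assigns default labels (`B<centre ppm to 4 decimals>`) where missing.
#' @param buckets data.frame with `ppm_min`, `ppm_max` (and optional `label`).
#' @export
bucketTable <- function(buckets) {
  buckets <- as.data.frame(buckets)
  if (!nrow(buckets)) {
    buckets <- data.frame(label = character(0), ppm_min = numeric(0),
                          ppm_max = numeric(0), stringsAsFactors = FALSE)
    return(new("BucketTable", buckets = buckets))
  }
  ctr <- (buckets$ppm_min + buckets$ppm_max) / 2
  buckets <- buckets[order(-ctr), , drop = FALSE]
  if (is.null(buckets$label))
    buckets$label <- defaultBucketLabels((buckets$ppm_min + buckets$ppm_max) / 2)
  rownames(buckets) <- NULL
  new("BucketTable", buckets = buckets[c("label", "ppm_min", "ppm_max")])
}

# stable bucket labels: centre ppm at 4 decimals, suffixed on collision
defaultBucketLabels <- function(centers) {
  lab <- sprintf("B%.4f", centers)
  while (anyDuplicated(lab)) {
    d <- duplicated(lab)
    lab[d] <- paste0(lab[d], "_2")
  }
  lab
}
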