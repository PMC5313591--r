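#' @rdname SpectrumSet-class
#' @export
setMethod("intensities", "SpectrumSet", function(x) x@intensities)

#' @rdname SpectrumSet-class
#' @export
setMethod("ppmAxis", "SpectrumSet", function(x) x@ppm)

#' @rdname SpectrumSet-class
#' @export
setMethod("sampleData", "SpectrumSet", function(x) x@sampleData)

#' @rdname SpectrumSet-class
#' @export
setMethod("sampleNames", "SpectrumSet", function(x) x@sampleData$sample_id)

#' @rdname SpectrumSet-class
#' @export
setMethod("excludedZones", "SpectrumSet", function(x) x@excluded)

#' @rdname SpectrumSet-class
#' @export
setMethod("provenance", "SpectrumSet", function(x) x@provenance)

#' @rdname SpectrumSet-class
#' @export
setMethod("nrow", "SpectrumSet", function(x) nrow(x@intensities))

#' @rdname SpectrumSet-class
#' @export
setMethod("ncol", "SpectrumSet", function(x) ncol(x@intensities))

setMethod("show", "SpectrumSet", function(object) {
  cat("SpectrumSet:", nrow(object@intensities), "spectra x",
      ncol(object@intensities), "points\n")
  cat("  ppm axis:", sprintf("%.4f .. %.4f", object@ppm[1],
      object@ppm[length(object@ppm)]), "\n")
  fac <- setdiff(colnames(object@sampleData), "sample_id")
  if (length(fac)) cat("  factors:", paste(fac, collapse = ", "), "\n")
  if (nrow(object@excluded))
    cat("  excluded zones:", nrow(object@excluded), "\n")
  if (length(object@provenance))
    cat("  provenance:", length(object@provenance), "commands\n")
})

setMethod("show", "FidRecord", function(object) {
  cat("FidRecord [", object@vendor, "] ", object@sampleId, ": ",
      length(object@signal), " complex points, sw ",
      sprintf("%.2f", object@swPpm), " ppm @ ",
      sprintf("%.2f", object@sfoMHz), " MHz\n", sep = "")
})

setMethod("show", "PpmZone", function(object) {
  cat(sprintf("PpmZone [%.4f, %.4f] ppm\n", object@ppmMin, object@ppmMax))
})

setMethod("show", "BucketTable", function(object) {
  cat("BucketTable:", nrow(object@buckets), "buckets\n")
  if (nrow(object@buckets)) print(utils::head(object@buckets, 5))
})

#' @rdname BucketTable-class
#' @export
setMethod("buckets", "BucketTable", function(x) x@buckets)

#' @rdname BucketTable-class
#' @export
setMethod("length", "BucketTable", function(x) nrow(x@buckets))

#' @describeIn BucketTable-class bucket table as a data.frame.
#' @param row.names,optional,... passed on conventionally (ignored).
#' @export
as.data.frame.BucketTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@buckets
}
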