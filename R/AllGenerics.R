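#' @rdname SpectrumSet-class
#' @param object,x an object.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("excludedZones", function(x) standardGeneric("excludedZones"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname BucketTable-class
#' @export
setGeneric("buckets", function(x) standardGeneric("buckets"))
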