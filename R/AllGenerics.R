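#' @rdname MarkerData-accessors
#' @export
setGeneric("genotypeMatrix", function(x, ...) standardGeneric("genotypeMatrix"))

#' @rdname MarkerData-accessors
#' @export
setGeneric("trait", function(x, ...) standardGeneric("trait"))

#' @rdname MarkerData-accessors
#' @export
setGeneric("markerIds", function(x, ...) standardGeneric("markerIds"))

#' @rdname MarkerData-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname MarkerData-accessors
#' @export
setGeneric("causalPairs", function(x, ...) standardGeneric("causalPairs"))

#' @rdname IntervalScheme-accessors
#' @export
setGeneric("nLevels", function(x, ...) standardGeneric("nLevels"))

#' @rdname IntervalScheme-accessors
#' @export
setGeneric("schemeBorders", function(x, ...) standardGeneric("schemeBorders"))

#' @rdname IntervalScheme-accessors
#' @export
setGeneric("schemeMidpoints", function(x, ...) standardGeneric("schemeMidpoints"))

#' @rdname SearchResult-accessors
#' @export
setGeneric("candidates", function(x, ...) standardGeneric("candidates"))

#' @rdname PenetranceGrid
#' @export
setGeneric("gridValues", function(x, ...) standardGeneric("gridValues"))
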