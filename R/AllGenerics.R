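#' @rdname internuclearDistances
#' @export
setGeneric("internuclearDistances",
           function(trace) standardGeneric("internuclearDistances"))

#' @rdname analyzeTrace
#' @export
setGeneric("analyzeTrace", function(trace, ...) standardGeneric("analyzeTrace"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname accessors
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname accessors
#' @export
setGeneric("rawDistances", function(x) standardGeneric("rawDistances"))

#' @rdname accessors
#' @export
setGeneric("correctedDistances",
           function(x) standardGeneric("correctedDistances"))

#' @rdname accessors
#' @export
setGeneric("gapClassifications",
           function(x) standardGeneric("gapClassifications"))

#' @rdname accessors
#' @export
setGeneric("binucleateFraction",
           function(x) standardGeneric("binucleateFraction"))

#' @rdname accessors
#' @export
setGeneric("dropoutFraction", function(x) standardGeneric("dropoutFraction"))

#' @rdname accessors
#' @export
setGeneric("cellArea", function(x, ...) standardGeneric("cellArea"))

#' @rdname accessors
#' @export
setGeneric("quantScale", function(x) standardGeneric("quantScale"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
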