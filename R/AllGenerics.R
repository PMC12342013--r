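#' @name cloneburst-generics
#' @title Accessor generics
#' @description Accessors for the core classes; use these instead of slot
#'   access.
#' @param x an object
#' @param ... passed to methods
NULL

#' @rdname cloneburst-generics
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))

#' @rdname cloneburst-generics
#' @export
setGeneric("cloneCounts", function(x, ...) standardGeneric("cloneCounts"))

#' @rdname cloneburst-generics
#' @export
setGeneric("sampleTotals", function(x, ...) standardGeneric("sampleTotals"))

#' @rdname cloneburst-generics
#' @export
setGeneric("sampleRichness", function(x, ...)
    standardGeneric("sampleRichness"))

#' @rdname cloneburst-generics
#' @export
setGeneric("cloneIds", function(x, ...) standardGeneric("cloneIds"))

#' @rdname cloneburst-generics
#' @export
setGeneric("clonePath", function(x, clone, ...) standardGeneric("clonePath"))

#' @rdname cloneburst-generics
#' @export
setGeneric("totalPath", function(x, ...) standardGeneric("totalPath"))

#' @rdname cloneburst-generics
#' @export
setGeneric("diffEvents", function(x, ...) standardGeneric("diffEvents"))

#' @rdname cloneburst-generics
#' @export
setGeneric("cloneRecords", function(x, ...) standardGeneric("cloneRecords"))

#' @rdname cloneburst-generics
#' @export
setGeneric("clusterCenters", function(x, ...)
    standardGeneric("clusterCenters"))

#' @rdname cloneburst-generics
#' @export
setGeneric("clusterWeights", function(x, ...)
    standardGeneric("clusterWeights"))

#' @rdname cloneburst-generics
#' @export
setGeneric("bestParams", function(x, ...) standardGeneric("bestParams"))

#' @rdname cloneburst-generics
#' @export
setGeneric("stageRecords", function(x, ...) standardGeneric("stageRecords"))

#' @rdname cloneburst-generics
#' @export
setGeneric("etaMultipliers", function(x, ...)
    standardGeneric("etaMultipliers"))

#' @rdname cloneburst-generics
#' @export
setGeneric("totalYield", function(x, ...) standardGeneric("totalYield"))
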