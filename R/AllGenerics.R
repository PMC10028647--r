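#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("subnetworks", function(x) standardGeneric("subnetworks"))

#' @rdname accessors
#' @export
setGeneric("subnetworkSet", function(x) standardGeneric("subnetworkSet"))

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname accessors
#' @export
setGeneric("edgeDensity", function(x) standardGeneric("edgeDensity"))

#' @rdname accessors
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname accessors
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @rdname accessors
#' @export
setGeneric("runsOf", function(x, subject) standardGeneric("runsOf"))

#' @rdname accessors
#' @export
setGeneric("overallIcc", function(x) standardGeneric("overallIcc"))

#' @rdname accessors
#' @export
setGeneric("reliabilityClass", function(x) standardGeneric("reliabilityClass"))

#' @rdname accessors
#' @export
setGeneric("perDensityIcc", function(x) standardGeneric("perDensityIcc"))
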