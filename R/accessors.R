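#' Accessors for temponet classes
#'
#' Small extractor functions for the S4 containers; use these instead of
#' reaching into slots.
#'
#' @param x an object of the documented class.
#' @param subject a subject id (for \code{runsOf}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nNodes", "RoiTimeSeries", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("nTimepoints", "RoiTimeSeries", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(x) x@trSeconds)

#' @rdname accessors
#' @export
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("runId", "RoiTimeSeries", function(x) x@runId)

#' Extract the signal matrix of a run
#' @param x a RoiTimeSeries.
#' @return numeric T x N matrix.
#' @export
signalMatrix <- function(x) {
  stopifnot(is(x, "RoiTimeSeries"))
  x@data
}

#' @rdname accessors
#' @export
setMethod("nNodes", "Parcellation", function(x) length(x@nodeIds))

#' @rdname accessors
#' @export
setMethod("nodeIds", "Parcellation", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("subnetworks", "Parcellation", function(x) {
  stats::setNames(x@subnetwork, x@nodeIds)
})

#' @rdname accessors
#' @export
setMethod("subnetworkSet", "Parcellation", function(x) x@subnetworkSet)

#' @rdname accessors
#' @export
setMethod("nNodes", "CorrelationStack", function(x) dim(x@layers)[1L])

#' @rdname accessors
#' @export
setMethod("nLayers", "CorrelationStack", function(x) dim(x@layers)[3L])

#' @rdname accessors
#' @export
setMethod("layers", "CorrelationStack", function(x) x@layers)

#' @rdname accessors
#' @export
setMethod("nNodes", "MultilayerNetwork", function(x) dim(x@layers)[1L])

#' @rdname accessors
#' @export
setMethod("nLayers", "MultilayerNetwork", function(x) dim(x@layers)[3L])

#' @rdname accessors
#' @export
setMethod("edgeDensity", "MultilayerNetwork", function(x) x@density)

#' @rdname accessors
#' @export
setMethod("layers", "MultilayerNetwork", function(x) x@layers)

#' @rdname accessors
#' @export
setMethod("adjacency", "StaticNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("edgeDensity", "StaticNetwork", function(x) x@density)

#' @rdname accessors
#' @export
setMethod("nNodes", "StaticNetwork", function(x) nrow(x@adjacency))

#' @rdname accessors
#' @export
setMethod("nSubjects", "Cohort", function(x) nrow(x@subjects))

#' @rdname accessors
#' @export
setMethod("nRuns", "Cohort", function(x) {
  if (length(x@runs) == 0L) 0L else length(x@runs[[1L]])
})

#' @rdname accessors
#' @export
setMethod("subjectTable", "Cohort", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("runsOf", "Cohort", function(x, subject) {
  x@runs[[as.character(subject)]]
})

#' @rdname accessors
#' @export
setMethod("overallIcc", "IccResult", function(x) x@overallIcc)

#' @rdname accessors
#' @export
setMethod("reliabilityClass", "IccResult", function(x) x@reliabilityClass)

#' @rdname accessors
#' @export
setMethod("perDensityIcc", "IccResult", function(x) x@perDensity)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: subject %s, run %s, %d timepoints x %d nodes, TR %.3g s\n",
              object@subjectId, object@runId,
              nrow(object@data), ncol(object@data), object@trSeconds))
})

setMethod("show", "Parcellation", function(object) {
  tab <- table(factor(object@subnetwork, levels = object@subnetworkSet))
  cat(sprintf("Parcellation: %d nodes in %d subnetworks\n",
              length(object@nodeIds), length(object@subnetworkSet)))
  print(tab)
})

setMethod("show", "Cohort", function(object) {
  s <- object@subjects
  cat(sprintf("Cohort: %d subjects (%d male, %d female), %d run(s) each\n",
              nrow(s), sum(s$sex == "male"), sum(s$sex == "female"),
              nRuns(object)))
  cat(sprintf("  age %.1f-%.1f y, mean FD %.3f-%.3f mm\n",
              min(s$age), max(s$age), min(s$meanFd), max(s$meanFd)))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: width %d TRs, step %d TRs\n",
              object@widthTr, object@stepTr))
})

setMethod("show", "CorrelationStack", function(object) {
  cat(sprintf("CorrelationStack: %d windows of %d x %d correlations\n",
              nLayers(object), nNodes(object), nNodes(object)))
})

setMethod("show", "MultilayerNetwork", function(object) {
  cat(sprintf("MultilayerNetwork: %d binary layers, %d nodes, density %.2f (%d edges/layer)\n",
              nLayers(object), nNodes(object), object@density,
              .edgeCount(object@density, nNodes(object))))
})

setMethod("show", "StaticNetwork", function(object) {
  cat(sprintf("StaticNetwork: %d nodes, density %.2f, %d edges\n",
              nNodes(object), object@density,
              sum(object@adjacency[upper.tri(object@adjacency)])))
})

setMethod("show", "TemporalClusteringResult", function(object) {
  cat(sprintf("TemporalClusteringResult: global %.4f; %d nodes, %d subnetworks\n",
              object@globalValue, length(object@nodal),
              length(object@subnetworkValues)))
})

setMethod("show", "IccResult", function(object) {
  cat(sprintf("IccResult [%s, %s]: overall ICC %.3f +/- %.3f (%s), %d densities\n",
              object@metricName, object@scope, object@overallIcc,
              object@overallSd, object@reliabilityClass,
              length(object@perDensity)))
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf("SynthSpec: %d subjects x %d runs, %d nodes, %d timepoints (TR %.2f s)\n",
              object@nSubjects, object@kRuns, object@nNodes,
              object@tPoints, object@trSeconds))
  cat(sprintf("  dwell: base %.1f, sex effect %.1f, age slope %.2f, sigma_subject %.1f, sigma_run %.1f\n",
              object@baseDwell, object@sexEffect, object@ageSlope,
              object@sigmaSubject, object@sigmaRun))
})
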