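#' @import methods
NULL

.defaultSubnetworks <- c(
  "default-mode", "salience", "visual", "subcortical", "auditory",
  "frontoparietal", "cinguloopercular", "sensorimotor", "attention"
)

#' Default subnetwork names
#'
#' The nine functional subsystems into which ROIs are grouped:
#' default-mode, salience, visual, subcortical, auditory, frontoparietal,
#' cinguloopercular, sensorimotor, and attention.
#'
#' @return Character vector of length 9.
#' @export
defaultSubnetworks <- function() .defaultSubnetworks

#' RoiTimeSeries: one run's ROI signal matrix
#'
#' Holds the T x N matrix of mean ROI signals for a single resting-state run
#' (T timepoints, N nodes), together with subject/run identifiers and the
#' repetition time (TR) in seconds.
#'
#' @slot data numeric matrix, T rows (timepoints) by N columns (nodes);
#'   column names are node ids.
#' @slot subjectId character scalar.
#' @slot runId character scalar.
#' @slot trSeconds positive numeric scalar, sampling interval in seconds.
#' @export
setClass("RoiTimeSeries",
  representation(
    data = "matrix",
    subjectId = "character",
    runId = "character",
    trSeconds = "numeric"
  )
)

setValidity("RoiTimeSeries", function(object) {
  x <- object@data
  if (!is.numeric(x)) {
    return("time-series data must be a numeric matrix")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    return(sprintf("need at least 2 timepoints and 2 nodes, got %d x %d",
                   nrow(x), ncol(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    return("time-series data contains missing or non-finite values")
  }
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- if (!is.null(colnames(x))) colnames(x)[bad[1L]] else bad[1L]
    return(sprintf("zero-variance column(s): first offender is column %s (index %d)",
                   nm, bad[1L]))
  }
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0) {
    return("trSeconds must be a single positive number")
  }
  TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data numeric T x N matrix (timepoints x nodes). Column names, if
#'   absent, default to \code{n1..nN}.
#' @param trSeconds repetition time in seconds.
#' @param subjectId,runId identifiers.
#' @return A validated \linkS4class{RoiTimeSeries}.
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(40), 10, 4), trSeconds = 0.72)
#' nNodes(ts)
#' @export
roiTimeSeries <- function(data, trSeconds, subjectId = "s1", runId = "r1") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("n", seq_len(ncol(data)))
  }
  new("RoiTimeSeries", data = data, subjectId = as.character(subjectId),
      runId = as.character(runId), trSeconds = as.numeric(trSeconds))
}

#' Parcellation: node-to-subnetwork assignment
#'
#' Maps each network node to exactly one subnetwork from a declared set
#' (by default the nine functional subsystems, \code{\link{defaultSubnetworks}}).
#' Node order in the parcellation defines node order everywhere downstream.
#'
#' @slot nodeIds character vector of unique node identifiers (length N).
#' @slot nodeLabels character vector of display labels.
#' @slot subnetwork character vector; \code{subnetwork[i]} is the subnetwork
#'   of node \code{nodeIds[i]}.
#' @slot subnetworkSet character vector of declared subnetwork names.
#' @export
setClass("Parcellation",
  representation(
    nodeIds = "character",
    nodeLabels = "character",
    subnetwork = "character",
    subnetworkSet = "character"
  )
)

setValidity("Parcellation", function(object) {
  n <- length(object@nodeIds)
  if (n < 1L) return("parcellation has no nodes")
  if (anyDuplicated(object@nodeIds)) {
    dup <- object@nodeIds[duplicated(object@nodeIds)][1L]
    return(sprintf("duplicate node id: %s", dup))
  }
  if (length(object@nodeLabels) != n || length(object@subnetwork) != n) {
    return("nodeIds, nodeLabels and subnetwork must have equal length")
  }
  if (anyNA(object@subnetwork) || any(object@subnetwork == "")) {
    return("every node must be assigned a subnetwork")
  }
  unknown <- setdiff(unique(object@subnetwork), object@subnetworkSet)
  if (length(unknown)) {
    return(sprintf("subnetwork name(s) not in the declared set: %s",
                   paste(unknown, collapse = ", ")))
  }
  empty <- setdiff(object@subnetworkSet, unique(object@subnetwork))
  if (length(empty)) {
    return(sprintf("declared subnetwork(s) with no member nodes: %s",
                   paste(empty, collapse = ", ")))
  }
  TRUE
})

#' Construct a Parcellation
#'
#' @param nodeIds character vector of unique node ids.
#' @param subnetwork character vector assigning each node to a subnetwork.
#' @param nodeLabels optional display labels (default: the ids).
#' @param subnetworkSet declared set of valid subnetwork names; defaults to
#'   the nine canonical functional subsystems. Every declared name must have
#'   at least one member so that subnetwork averages are always defined.
#' @return A validated \linkS4class{Parcellation}.
#' @export
parcellation <- function(nodeIds, subnetwork, nodeLabels = nodeIds,
                         subnetworkSet = defaultSubnetworks()) {
  new("Parcellation",
      nodeIds = as.character(nodeIds),
      nodeLabels = as.character(nodeLabels),
      subnetwork = as.character(subnetwork),
      subnetworkSet = as.character(subnetworkSet))
}

#' Cohort: subjects, covariates and their runs
#'
#' A cohort table (one row per subject: sex, age, education years, mean
#' framewise displacement) plus, per subject, a list of
#' \linkS4class{RoiTimeSeries} runs. All subjects must have the same number
#' of runs; reliability analyses additionally require k >= 2.
#'
#' @slot subjects data.frame with columns subjectId, sex (factor with levels
#'   male, female), age, education, meanFd.
#' @slot runs named list (by subjectId) of lists of RoiTimeSeries.
#' @export
setClass("Cohort",
  representation(
    subjects = "data.frame",
    runs = "list"
  )
)

setValidity("Cohort", function(object) {
  s <- object@subjects
  need <- c("subjectId", "sex", "age", "education", "meanFd")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    return(sprintf("subjects table lacks column(s): %s",
                   paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(s$subjectId)) return("duplicate subject ids")
  if (!is.factor(s$sex) || !identical(levels(s$sex), c("male", "female"))) {
    return("sex must be a factor with levels male, female (in that order)")
  }
  for (cv in c("age", "education", "meanFd")) {
    if (anyNA(s[[cv]])) return(sprintf("missing values in covariate %s", cv))
  }
  if (any(s$meanFd < 0)) return("meanFd must be nonnegative")
  if (!setequal(names(object@runs), as.character(s$subjectId))) {
    return("runs list names must match subject ids")
  }
  k <- vapply(object@runs, length, integer(1L))
  if (length(unique(k)) > 1L) {
    return("all subjects must have the same number of runs")
  }
  TRUE
})

#' Construct a Cohort
#'
#' @param subjects data.frame with columns subjectId, sex, age, education,
#'   meanFd. \code{sex} may be character ("male"/"female") or a factor.
#' @param runs named list (by subjectId) of lists of
#'   \linkS4class{RoiTimeSeries}.
#' @return A validated \linkS4class{Cohort}.
#' @export
cohort <- function(subjects, runs) {
  subjects <- as.data.frame(subjects)
  subjects$subjectId <- as.character(subjects$subjectId)
  if (!is.factor(subjects$sex)) {
    subjects$sex <- factor(as.character(subjects$sex),
                           levels = c("male", "female"))
  }
  new("Cohort", subjects = subjects, runs = runs[subjects$subjectId])
}

#' WindowSpec: sliding-window geometry
#'
#' Width and step of the sliding window, both in TR units. The reference
#' configuration is width 139 TRs and step 8 TRs (100.08 s and 5.76 s at
#' TR = 0.72 s), which tiles a 1200-timepoint run into 133 windows.
#'
#' @slot widthTr positive integer, window width in TRs.
#' @slot stepTr positive integer, sliding step in TRs.
#' @export
setClass("WindowSpec",
  representation(widthTr = "integer", stepTr = "integer")
)

setValidity("WindowSpec", function(object) {
  if (length(object@widthTr) != 1L || object@widthTr < 2L) {
    return("widthTr must be a single integer >= 2")
  }
  if (length(object@stepTr) != 1L || object@stepTr < 1L) {
    return("stepTr must be a single integer >= 1")
  }
  TRUE
})

#' @rdname WindowSpec-class
#' @param widthTr window width in TRs.
#' @param stepTr sliding step in TRs.
#' @export
windowSpec <- function(widthTr = 139L, stepTr = 8L) {
  new("WindowSpec", widthTr = as.integer(widthTr), stepTr = as.integer(stepTr))
}

#' CorrelationStack: windowed Pearson correlation matrices
#'
#' @slot layers numeric array N x N x W of Pearson correlation matrices,
#'   one per window, unit diagonal.
#' @slot windowStarts integer vector of 0-based window start offsets.
#' @slot widthTr integer window width used.
#' @export
setClass("CorrelationStack",
  representation(layers = "array", windowStarts = "integer",
                 widthTr = "integer")
)

setValidity("CorrelationStack", function(object) {
  d <- dim(object@layers)
  if (length(d) != 3L || d[1L] != d[2L]) {
    return("layers must be an N x N x W array")
  }
  if (d[3L] != length(object@windowStarts)) {
    return("number of layers must match windowStarts")
  }
  off <- object@layers
  if (any(off < -1 - 1e-8 | off > 1 + 1e-8)) {
    return("correlations outside [-1, 1]")
  }
  TRUE
})

#' MultilayerNetwork: binary dynamic network at one density
#'
#' An ordered stack of W binary, symmetric, zero-diagonal N x N adjacency
#' layers, each with exactly round(density * N(N-1)/2) edges.
#'
#' @slot layers integer array N x N x W with entries in {0, 1}.
#' @slot density edge density in (0, 1].
#' @slot windowStarts integer 0-based window start offsets.
#' @export
setClass("MultilayerNetwork",
  representation(layers = "array", density = "numeric",
                 windowStarts = "integer")
)

setValidity("MultilayerNetwork", function(object) {
  d <- dim(object@layers)
  if (length(d) != 3L || d[1L] != d[2L]) {
    return("layers must be an N x N x W array")
  }
  if (!all(object@layers %in% c(0L, 1L))) {
    return("adjacency entries must be 0 or 1")
  }
  if (length(object@density) != 1L || object@density <= 0 ||
      object@density > 1) {
    return("density must be a single value in (0, 1]")
  }
  n <- d[1L]
  kExp <- .edgeCount(object@density, n)
  for (w in seq_len(d[3L])) {
    a <- object@layers[, , w]
    if (any(diag(a) != 0L)) return("nonzero diagonal in a layer")
    if (!identical(a, t(a))) return("asymmetric adjacency in a layer")
    if (sum(a[upper.tri(a)]) != kExp) {
      return(sprintf("layer %d has %d edges, expected %d",
                     w, sum(a[upper.tri(a)]), kExp))
    }
  }
  TRUE
})

#' StaticNetwork: binary network from the whole run
#'
#' @slot adjacency integer N x N binary symmetric matrix, zero diagonal.
#' @slot density edge density used for thresholding.
#' @export
setClass("StaticNetwork",
  representation(adjacency = "matrix", density = "numeric")
)

setValidity("StaticNetwork", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!all(a %in% c(0L, 1L))) return("adjacency entries must be 0 or 1")
  if (any(diag(a) != 0L)) return("nonzero diagonal")
  if (!identical(unname(a), unname(t(a)))) return("adjacency must be symmetric")
  TRUE
})

#' TemporalClusteringResult: nodal, subnetwork and global values
#'
#' @slot nodal numeric vector of per-node temporal clustering coefficients.
#' @slot globalValue unweighted mean of the nodal values.
#' @slot subnetworkValues named numeric vector, one unweighted mean per
#'   subnetwork.
#' @export
setClass("TemporalClusteringResult",
  representation(nodal = "numeric", globalValue = "numeric",
                 subnetworkValues = "numeric")
)

#' IccResult: test-retest reliability of one metric at one scope
#'
#' Per-density ICC(3,1) values plus the density-averaged "overall" ICC, its
#' SD across densities, and the qualitative reliability class.
#'
#' @slot scope character scope label (global, subnetwork:<name>, node:<id>).
#' @slot metricName character metric name.
#' @slot perDensity named numeric vector, ICC at each density.
#' @slot overallIcc mean ICC across densities.
#' @slot overallSd SD of ICC across densities.
#' @slot reliabilityClass one of poor, moderate, good, excellent, undefined.
#' @export
setClass("IccResult",
  representation(scope = "character", metricName = "character",
                 perDensity = "numeric", overallIcc = "numeric",
                 overallSd = "numeric", reliabilityClass = "character")
)

#' SynthSpec: parameters of the synthetic cohort generator
#'
#' The generator draws, per subject and run, a latent regime dwell time
#' lambda (timepoints) = baseDwell + sexEffect * 1[female] +
#' ageSlope * (age - mean age) + b_subject + e_run, and emits a
#' regime-switching Gaussian time series whose windowed connectivity
#' persists for about lambda timepoints per covariance regime.
#'
#' @slot nSubjects number of subjects.
#' @slot kRuns runs per subject.
#' @slot nNodes number of nodes.
#' @slot subnetworkSizes integer vector of nodes per subnetwork (sums to
#'   nNodes); names taken from \code{\link{defaultSubnetworks}} unless given.
#' @slot tPoints timepoints per run.
#' @slot trSeconds repetition time, seconds.
#' @slot baseDwell mean regime dwell time in timepoints.
#' @slot sexEffect additive dwell shift for females (timepoints).
#' @slot ageSlope dwell change per year of age.
#' @slot ageRange uniform age range in years.
#' @slot sigmaSubject SD of the subject random effect on dwell.
#' @slot sigmaRun SD of the run-level dwell noise.
#' @slot noiseSd observation noise SD added on top of the regime signal.
#' @slot regimeRho within-community signal correlation of a regime.
#' @slot nCommunities latent communities the subnetworks are shuffled into
#'   at each regime switch.
#' @slot seed integer RNG seed.
#' @export
setClass("SynthSpec",
  representation(
    nSubjects = "integer", kRuns = "integer", nNodes = "integer",
    subnetworkSizes = "integer", tPoints = "integer", trSeconds = "numeric",
    baseDwell = "numeric", sexEffect = "numeric", ageSlope = "numeric",
    ageRange = "numeric", sigmaSubject = "numeric", sigmaRun = "numeric",
    noiseSd = "numeric", regimeRho = "numeric", nCommunities = "integer",
    seed = "integer"
  )
)

setValidity("SynthSpec", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  if (object@kRuns < 1L) return("kRuns must be >= 1")
  if (sum(object@subnetworkSizes) != object@nNodes) {
    return("subnetworkSizes must sum to nNodes")
  }
  if (any(object@subnetworkSizes < 1L)) {
    return("every subnetwork needs at least one node")
  }
  if (object@tPoints < 2L) return("tPoints must be >= 2")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  if (object@baseDwell <= 0) return("baseDwell must be positive")
  if (object@sigmaSubject < 0 || object@sigmaRun < 0 || object@noiseSd < 0) {
    return("all SDs must be nonnegative")
  }
  if (object@regimeRho <= 0 || object@regimeRho >= 1) {
    return("regimeRho must be in (0, 1)")
  }
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0) {
    return("ageRange must be c(lo, hi) with lo <= hi")
  }
  TRUE
})
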