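#' Temporal clustering coefficients of a binary multilayer network
#'
#' The nodal temporal clustering coefficient of node i quantifies how
#' consistently its neighbour set persists across consecutive layers:
#' \deqn{C_i = \frac{1}{T-1} \sum_{t=1}^{T-1}
#'   \frac{\sum_j a_{ij}(t) a_{ij}(t+1)}
#'        {\sqrt{\sum_j a_{ij}(t) \sum_j a_{ij}(t+1)}}}
#' where a_ij(t) is the binary adjacency in layer t and T is the number of
#' layers. Each term is the neighbour overlap between layers t and t+1
#' normalized by the geometric mean of the two degrees, so C_i lies in
#' [0, 1] (Cauchy-Schwarz). If node i is isolated in layer t or t+1, that
#' transition contributes 0 to the sum while the 1/(T-1) normalization is
#' kept; this keeps the coefficient defined at very low densities.
#'
#' @param net a \linkS4class{MultilayerNetwork} with at least 2 layers, or
#'   a plain binary N x N x W array (any symmetric zero-diagonal stack).
#' @return named numeric vector of length N with values in [0, 1].
#' @seealso \code{\link{aggregateTemporalClustering}} for subnetwork and
#'   global summaries.
#' @export
nodalTemporalClustering <- function(net) {
  a <- if (is(net, "MultilayerNetwork")) net@layers else net
  stopifnot(is.array(a), length(dim(a)) == 3L)
  w <- dim(a)[3L]
  if (w < 2L) {
    stop("temporal clustering needs at least 2 layers (consecutive pairs)")
  }
  n <- dim(a)[1L]
  # degrees per layer: N x W
  deg <- apply(a, 3L, rowSums)
  overlap <- matrix(0, n, w - 1L)
  for (t in seq_len(w - 1L)) {
    overlap[, t] <- rowSums(a[, , t] * a[, , t + 1L])
  }
  denom <- sqrt(deg[, -w, drop = FALSE] * deg[, -1L, drop = FALSE])
  ratio <- ifelse(denom > 0, overlap / pmax(denom, 1), 0)
  ci <- rowSums(ratio) / (w - 1L)
  names(ci) <- dimnames(a)[[1L]]
  ci
}

#' Aggregate nodal temporal clustering to subnetwork and global scope
#'
#' The global coefficient is the unweighted mean over all nodes; each
#' subnetwork coefficient is the unweighted mean over its member nodes.
#'
#' @param nodal numeric vector of nodal values, in parcellation node order.
#' @param parc a \linkS4class{Parcellation} of matching length.
#' @return A \linkS4class{TemporalClusteringResult}.
#' @export
aggregateTemporalClustering <- function(nodal, parc) {
  .aggregateNodal(nodal, parc)
}

# unweighted global / per-subnetwork means of any nodal metric vector
.aggregateNodal <- function(nodal, parc) {
  stopifnot(is(parc, "Parcellation"))
  if (length(nodal) != nNodes(parc)) {
    stop(sprintf("nodal vector length (%d) does not match parcellation (%d nodes)",
                 length(nodal), nNodes(parc)))
  }
  grp <- factor(parc@subnetwork, levels = parc@subnetworkSet)
  subMeans <- tapply(nodal, grp, mean)
  new("TemporalClusteringResult",
      nodal = stats::setNames(as.numeric(nodal), parc@nodeIds),
      globalValue = mean(nodal),
      subnetworkValues = stats::setNames(as.numeric(subMeans), levels(grp)))
}

# scope labels used throughout MetricTable records
.scopeLabels <- function(parc) {
  c("global",
    paste0("subnetwork:", parc@subnetworkSet),
    paste0("node:", parc@nodeIds))
}

.resultRecord <- function(res, parc, subject, run, density, metric) {
  data.frame(
    subject = subject, run = run, density = density,
    scope = .scopeLabels(parc),
    metric = metric,
    value = c(res@globalValue, res@subnetworkValues, res@nodal),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Temporal clustering metric table for one run
#'
#' Builds the multilayer networks of one run over a density sweep and
#' records the temporal clustering coefficient at global, subnetwork and
#' nodal scope for every density, in long form.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param spec a \linkS4class{WindowSpec}.
#' @param densities density sweep, default \code{\link{defaultDensityGrid}()}.
#' @param parc a \linkS4class{Parcellation} matching the node order of
#'   \code{ts}.
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return A metric table data.frame with columns subject, run, density,
#'   scope, metric, value; metric is \code{"temporal_clustering"}.
#' @export
runTemporalPipeline <- function(ts, spec = windowSpec(),
                                densities = defaultDensityGrid(),
                                parc, rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  .checkNodeOrder(ts, parc)
  nets <- buildMultilayer(ts, spec, densities, rankBy)
  out <- lapply(seq_along(densities), function(i) {
    ci <- nodalTemporalClustering(nets[[i]])
    res <- aggregateTemporalClustering(ci, parc)
    .resultRecord(res, parc, subjectId(ts), runId(ts), densities[i],
                  "temporal_clustering")
  })
  do.call(rbind, out)
}

.checkNodeOrder <- function(ts, parc) {
  stopifnot(is(ts, "RoiTimeSeries"), is(parc, "Parcellation"))
  if (nNodes(ts) != nNodes(parc)) {
    stop(sprintf("time series has %d nodes but parcellation has %d",
                 nNodes(ts), nNodes(parc)))
  }
  cn <- colnames(ts@data)
  if (!is.null(cn) && !identical(cn, parc@nodeIds)) {
    stop("time-series column order does not match parcellation node order")
  }
  invisible(TRUE)
}
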