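#' Static comparator metrics
#'
#' Binary clustering coefficient and local efficiency of the static network
#' built from the whole run, using the standard binary (Rubinov & Sporns)
#' definitions: triangles over possible neighbour pairs for clustering, and
#' mean inverse shortest-path length within the neighbour-induced subgraph
#' for local efficiency. Nodes with degree < 2 score 0 on both.
#'
#' @name static_metrics
NULL

#' Binary clustering coefficient
#'
#' C_i = 2 t_i / (k_i (k_i - 1)), with t_i the number of triangles through
#' node i and k_i its degree; C_i = 0 when k_i < 2.
#'
#' @param net a \linkS4class{StaticNetwork} or a plain binary symmetric
#'   adjacency matrix.
#' @return named numeric vector in [0, 1].
#' @export
staticClustering <- function(net) {
  a <- if (is(net, "StaticNetwork")) net@adjacency else net
  stopifnot(is.matrix(a))
  storage.mode(a) <- "double"
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  names(ci) <- rownames(a)
  ci
}

#' Binary local efficiency
#'
#' E_loc(i) = mean over ordered neighbour pairs (j, h) of 1 / d_jh(G_i),
#' where d_jh(G_i) is the shortest-path length between j and h in the
#' subgraph induced by the neighbours of i (node i itself excluded).
#' Unreachable pairs contribute 0 but stay in the normalizer k_i (k_i - 1);
#' E_loc(i) = 0 when k_i < 2.
#'
#' @param net a \linkS4class{StaticNetwork} or a plain binary symmetric
#'   adjacency matrix.
#' @return named numeric vector in [0, 1].
#' @export
localEfficiency <- function(net) {
  a <- if (is(net, "StaticNetwork")) net@adjacency else net
  stopifnot(is.matrix(a))
  n <- nrow(a)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L)
    ki <- length(nb)
    if (ki < 2L) next
    sub <- a[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    d <- igraph::distances(g)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    eff[i] <- 2 * sum(inv) / (ki * (ki - 1))
  }
  names(eff) <- rownames(a)
  eff
}

#' Static metric table for one run
#'
#' Builds the whole-run static network at every density and records the
#' clustering coefficient and local efficiency at global, subnetwork and
#' nodal scope, in the same long form as the temporal pipeline. Global and
#' subnetwork values are unweighted means of the nodal values.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param densities density sweep, default \code{\link{defaultDensityGrid}()}.
#' @param parc a \linkS4class{Parcellation}.
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return metric table data.frame; metrics are \code{"clustering"} and
#'   \code{"local_efficiency"}.
#' @export
runStaticPipeline <- function(ts, densities = defaultDensityGrid(), parc,
                              rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  .checkNodeOrder(ts, parc)
  r <- stats::cor(ts@data)
  out <- lapply(densities, function(d) {
    net <- new("StaticNetwork",
               adjacency = thresholdProportional(r, d, rankBy), density = d)
    cl <- staticClustering(net)
    le <- localEfficiency(net)
    rbind(
      .resultRecord(aggregateTemporalClustering(cl, parc), parc,
                    subjectId(ts), runId(ts), d, "clustering"),
      .resultRecord(aggregateTemporalClustering(le, parc), parc,
                    subjectId(ts), runId(ts), d, "local_efficiency")
    )
  })
  do.call(rbind, out)
}
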