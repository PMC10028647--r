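#' Cohort-level metric computation
#'
#' Runs the dynamic and/or static pipelines for every run of every subject
#' and stacks the results into one long-form metric table.
#'
#' @param coh a \linkS4class{Cohort}.
#' @param parc a \linkS4class{Parcellation}.
#' @param spec a \linkS4class{WindowSpec} for the dynamic pipeline.
#' @param densities density sweep.
#' @param metrics any of \code{"temporal_clustering"}, \code{"clustering"},
#'   \code{"local_efficiency"}.
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return metric table data.frame (subject, run, density, scope, metric,
#'   value).
#' @export
computeCohortMetrics <- function(coh, parc, spec = windowSpec(),
                                 densities = defaultDensityGrid(),
                                 metrics = c("temporal_clustering",
                                             "clustering",
                                             "local_efficiency"),
                                 rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  metrics <- match.arg(metrics, several.ok = TRUE)
  doTemporal <- "temporal_clustering" %in% metrics
  staticMetrics <- intersect(metrics, c("clustering", "local_efficiency"))
  out <- list()
  for (sid in subjectTable(coh)$subjectId) {
    for (run in runsOf(coh, sid)) {
      if (doTemporal) {
        out[[length(out) + 1L]] <-
          runTemporalPipeline(run, spec, densities, parc, rankBy)
      }
      if (length(staticMetrics)) {
        st <- runStaticPipeline(run, densities, parc, rankBy)
        out[[length(out) + 1L]] <-
          st[st$metric %in% staticMetrics, , drop = FALSE]
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Density-mean global temporal clustering per subject
#'
#' Lightweight path for simulation studies: computes, for every run of
#' every subject, the global temporal clustering coefficient at each
#' density, averages over the density grid and then over runs, and returns
#' one value per subject. Avoids building nodal/subnetwork records.
#'
#' @inheritParams computeCohortMetrics
#' @return data.frame with columns subjectId, value.
#' @export
subjectGlobalTemporalClustering <- function(coh, spec = windowSpec(),
                                            densities = defaultDensityGrid(),
                                            rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  ids <- subjectTable(coh)$subjectId
  vals <- vapply(ids, function(sid) {
    runVals <- vapply(runsOf(coh, sid), function(run) {
      stack <- windowCorrelations(run, spec)
      mean(colMeans(.globalTemporalClusteringSweep(stack, densities, rankBy)))
    }, numeric(1L))
    mean(runVals)
  }, numeric(1L))
  data.frame(subjectId = ids, value = unname(vals),
             stringsAsFactors = FALSE)
}

#' Global temporal clustering of one run across a density sweep
#'
#' Computes, for a single run, the global temporal clustering coefficient
#' at every requested density without materializing binary layer stacks
#' (see Details). Results are identical to running
#' \code{\link{buildMultilayer}} plus \code{\link{nodalTemporalClustering}}
#' and averaging over nodes.
#'
#' @details An edge is present at density d iff its rank position among
#' the window's correlations (value descending, ties by lexicographic pair
#' order) is at most the retained edge count, so one ranking per window
#' serves the whole sweep.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param spec a \linkS4class{WindowSpec}.
#' @param densities density sweep.
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return data.frame with columns density, value.
#' @export
runGlobalTemporalClustering <- function(ts, spec = windowSpec(),
                                        densities = defaultDensityGrid(),
                                        rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  stack <- windowCorrelations(ts, spec)
  sw <- .globalTemporalClusteringSweep(stack, densities, rankBy)
  data.frame(density = densities, value = rowMeans(sw))
}

# Global temporal clustering at every density, computed from edge rank
# positions instead of materialized adjacency stacks. An edge is present
# at density d iff its rank position (value descending, lexicographic
# pair order breaking ties -- identical to thresholdProportional) is
# <= edgeCount(d). Returns a densities x nodes matrix of nodal means over
# window transitions; global value at a density is the row mean.
.globalTemporalClusteringSweep <- function(stack, densities, rankBy) {
  n <- nNodes(stack)
  w <- nLayers(stack)
  if (w < 2L) stop("temporal clustering needs at least 2 layers")
  pairs <- .lexPairs(n)
  m <- nrow(pairs)
  # node-by-edge incidence
  inc <- matrix(0, n, m)
  inc[cbind(pairs[, 1L], seq_len(m))] <- 1
  inc[cbind(pairs[, 2L], seq_len(m))] <- 1
  kVec <- .edgeCount(densities, n)
  rankPos <- matrix(0L, m, w)
  for (t in seq_len(w)) {
    vals <- stack@layers[, , t][pairs]
    if (rankBy == "absolute") vals <- abs(vals)
    rankPos[order(-vals, seq_len(m)), t] <- seq_len(m)
  }
  acc <- matrix(0, length(kVec), n)   # densities x nodes
  degNext <- inc %*% outer(rankPos[, 1L], kVec, "<=")  # n x D
  for (t in seq_len(w - 1L)) {
    degT <- degNext
    degNext <- inc %*% outer(rankPos[, t + 1L], kVec, "<=")
    joint <- pmax(rankPos[, t], rankPos[, t + 1L])
    ov <- inc %*% outer(joint, kVec, "<=")
    denom <- sqrt(degT * degNext)
    acc <- acc + t(ifelse(denom > 0, ov / pmax(denom, 1), 0))
  }
  acc / (w - 1L)
}

#' Run the full analysis pipeline on a cohort
#'
#' Convenience wrapper: computes run-level metrics, the ICC reliability
#' table across runs, run-averaged metrics, and the global-scope sex
#' contrast, interaction screen and age correlation.
#'
#' @inheritParams computeCohortMetrics
#' @param globalFamily,subnetworkFamily Bonferroni family sizes for
#'   global-scope and subnetwork-scope tests (defaults 2 and 18: two
#'   questions per scope family).
#' @return list with elements \code{metrics}, \code{icc} (list of
#'   \linkS4class{IccResult}), \code{averaged}, \code{sex}, \code{age},
#'   \code{interaction} (data.frames).
#' @export
runCohortPipeline <- function(coh, parc, spec = windowSpec(),
                              densities = defaultDensityGrid(),
                              metrics = c("temporal_clustering",
                                          "clustering",
                                          "local_efficiency"),
                              rankBy = c("signed", "absolute"),
                              globalFamily = 2L, subnetworkFamily = 18L) {
  rankBy <- match.arg(rankBy)
  tab <- computeCohortMetrics(coh, parc, spec, densities, metrics, rankBy)
  iccRes <- if (nRuns(coh) >= 2L) {
    iccTable(tab, coh, scopes = c("global",
                                  paste0("subnetwork:", parc@subnetworkSet)))
  } else NULL
  avg <- averageRuns(tab)
  metricNames <- unique(tab$metric)
  subScopes <- paste0("subnetwork:", parc@subnetworkSet)
  sexRows <- list()
  ageRows <- list()
  intRows <- list()
  for (m in metricNames) {
    sexRows[[length(sexRows) + 1L]] <-
      sexContrast(avg, coh, "global", m, globalFamily)
    ageRows[[length(ageRows) + 1L]] <-
      ageCorrelation(avg, coh, "global", m, globalFamily)
    intRows[[length(intRows) + 1L]] <-
      interactionScreen(avg, coh, "global", m, globalFamily)
    for (sc in subScopes) {
      sexRows[[length(sexRows) + 1L]] <-
        sexContrast(avg, coh, sc, m, subnetworkFamily)
      ageRows[[length(ageRows) + 1L]] <-
        ageCorrelation(avg, coh, sc, m, subnetworkFamily)
    }
  }
  list(metrics = tab, icc = iccRes, averaged = avg,
       sex = do.call(rbind, sexRows),
       age = do.call(rbind, ageRows),
       interaction = do.call(rbind, intRows))
}
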