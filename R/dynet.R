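#' Sliding-window dynamic network construction
#'
#' The dynamic network pipeline segments a run into overlapping windows,
#' computes window-wise Pearson correlation matrices, and binarizes each
#' window by proportional thresholding: at density d, the
#' round(d * N(N-1)/2) strongest connections are kept and set to 1.
#'
#' @name dynet
NULL

# number of retained edges at a density; round-half-away-from-zero
.edgeCount <- function(density, n) {
  as.integer(floor(density * n * (n - 1) / 2 + 0.5))
}

# upper-triangle node pairs in ascending (i, j) lexicographic order
.lexPairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Plan sliding windows
#'
#' Tiles \code{tPoints} timepoints with windows of \code{widthTr} TRs moved
#' by \code{stepTr} TRs. Windows are half-open 0-based intervals
#' \code{[start, start + width)}; trailing timepoints that do not fill a
#' complete window are discarded, so the window count is
#' \code{floor((T - width) / step) + 1}.
#'
#' @param tPoints number of timepoints in the run.
#' @param spec a \linkS4class{WindowSpec}.
#' @return data.frame with 0-based columns \code{start}, \code{end}
#'   (half-open) and a \code{window} index.
#' @examples
#' nrow(planWindows(1200, windowSpec(139, 8)))  # 133
#' @export
planWindows <- function(tPoints, spec = windowSpec()) {
  stopifnot(is(spec, "WindowSpec"))
  tPoints <- as.integer(tPoints)
  if (spec@widthTr > tPoints) {
    stop(sprintf("window width (%d) exceeds run length (%d)",
                 spec@widthTr, tPoints))
  }
  starts <- seq.int(0L, tPoints - spec@widthTr, by = spec@stepTr)
  data.frame(window = seq_along(starts),
             start = starts,
             end = starts + spec@widthTr)
}

#' Window geometry in seconds
#'
#' Converts a window specification to seconds at a given TR, e.g. 139 TRs
#' at TR = 0.72 s is a 100.08 s window and an 8-TR step is 5.76 s.
#'
#' @param spec a \linkS4class{WindowSpec}.
#' @param trSeconds repetition time in seconds.
#' @return named numeric vector with elements \code{width} and \code{step}.
#' @export
windowSeconds <- function(spec, trSeconds) {
  stopifnot(is(spec, "WindowSpec"), trSeconds > 0)
  c(width = spec@widthTr * trSeconds, step = spec@stepTr * trSeconds)
}

#' Window-wise Pearson correlations
#'
#' Computes, for every planned window, the N x N Pearson correlation matrix
#' of the windowed signal segment.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param spec a \linkS4class{WindowSpec}.
#' @return A \linkS4class{CorrelationStack}.
#' @export
windowCorrelations <- function(ts, spec = windowSpec()) {
  stopifnot(is(ts, "RoiTimeSeries"))
  x <- ts@data
  plan <- planWindows(nrow(x), spec)
  n <- ncol(x)
  w <- nrow(plan)
  arr <- array(NA_real_, dim = c(n, n, w),
               dimnames = list(colnames(x), colnames(x), NULL))
  for (t in seq_len(w)) {
    seg <- x[(plan$start[t] + 1L):plan$end[t], , drop = FALSE]
    v <- .colVars(seg)
    if (any(v == 0)) {
      bad <- which(v == 0)[1L]
      stop(sprintf("zero-variance signal for node %s in window %d",
                   colnames(x)[bad], t))
    }
    arr[, , t] <- stats::cor(seg)
  }
  new("CorrelationStack", layers = arr,
      windowStarts = as.integer(plan$start), widthTr = spec@widthTr)
}

.colVars <- function(m) {
  mu <- colMeans(m)
  colMeans(m * m) - mu * mu
}

#' Proportional thresholding of a correlation matrix
#'
#' Keeps the k = round(density * N(N-1)/2) strongest off-diagonal
#' connections and sets them to 1, all others to 0. "Strongest" ranks by
#' signed correlation by default (\code{rankBy = "signed"}); set
#' \code{rankBy = "absolute"} to rank by magnitude. Ties at the cutoff are
#' broken deterministically by ascending (i, j) lexicographic pair order.
#'
#' @param corr symmetric numeric matrix; the diagonal is ignored.
#' @param density fraction of possible edges to keep, in (0, 1].
#' @param rankBy rank connections by \code{"signed"} value or
#'   \code{"absolute"} value.
#' @return integer binary adjacency matrix (symmetric, zero diagonal).
#' @examples
#' r <- cor(matrix(rnorm(80), 20, 4))
#' a <- thresholdProportional(r, 0.5)
#' sum(a[upper.tri(a)])  # 3 of the 6 possible edges
#' @export
thresholdProportional <- function(corr, density,
                                  rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  n <- nrow(corr)
  stopifnot(n == ncol(corr), density > 0, density <= 1)
  pairs <- .lexPairs(n)
  vals <- corr[pairs]
  if (rankBy == "absolute") vals <- abs(vals)
  k <- .edgeCount(density, n)
  adj <- matrix(0L, n, n, dimnames = dimnames(corr))
  if (k == 0L) {
    warning("density too low: zero edges retained")
    return(adj)
  }
  # stable sort: value descending, then lexicographic pair order
  keep <- order(-vals, seq_along(vals))[seq_len(k)]
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj[pairs[keep, c(2L, 1L), drop = FALSE]] <- 1L
  adj
}

#' Default density sweep
#'
#' Densities from 1% to 50% in 1% increments (50 levels).
#'
#' @return numeric vector of length 50.
#' @export
defaultDensityGrid <- function() seq(0.01, 0.50, by = 0.01)

#' Build binary multilayer networks over a density sweep
#'
#' Computes the window correlation stack once, then thresholds every window
#' at every requested density.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param spec a \linkS4class{WindowSpec}.
#' @param densities numeric vector of densities in (0, 1];
#'   default \code{\link{defaultDensityGrid}()}.
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return named list (by density) of \linkS4class{MultilayerNetwork}.
#' @export
buildMultilayer <- function(ts, spec = windowSpec(),
                            densities = defaultDensityGrid(),
                            rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  stack <- windowCorrelations(ts, spec)
  multilayerFromStack(stack, densities, rankBy)
}

#' Threshold an existing correlation stack at several densities
#'
#' @param stack a \linkS4class{CorrelationStack}.
#' @param densities numeric vector of densities in (0, 1].
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return named list (by density) of \linkS4class{MultilayerNetwork}.
#' @export
multilayerFromStack <- function(stack, densities = defaultDensityGrid(),
                                rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  stopifnot(is(stack, "CorrelationStack"),
            all(densities > 0), all(densities <= 1))
  n <- nNodes(stack)
  w <- nLayers(stack)
  pairs <- .lexPairs(n)
  # one stable ranking per window serves every density
  ranks <- matrix(0L, nrow(pairs), w)
  for (t in seq_len(w)) {
    vals <- stack@layers[, , t][pairs]
    if (rankBy == "absolute") vals <- abs(vals)
    ranks[, t] <- order(-vals, seq_along(vals))
  }
  out <- lapply(densities, function(d) {
    k <- .edgeCount(d, n)
    arr <- array(0L, dim = c(n, n, w),
                 dimnames = dimnames(stack@layers))
    if (k == 0L) {
      warning(sprintf("density %.3g too low: zero edges retained", d))
    } else {
      for (t in seq_len(w)) {
        keep <- ranks[seq_len(k), t]
        a <- matrix(0L, n, n)
        a[pairs[keep, , drop = FALSE]] <- 1L
        a[pairs[keep, c(2L, 1L), drop = FALSE]] <- 1L
        arr[, , t] <- a
      }
    }
    new("MultilayerNetwork", layers = arr, density = d,
        windowStarts = stack@windowStarts)
  })
  names(out) <- formatC(densities, format = "g")
  out
}

#' Build the static network of a whole run
#'
#' Pearson correlation over the full run, then proportional thresholding
#' with the same ranking and tie rules as the dynamic pipeline.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param density edge density in (0, 1].
#' @param rankBy see \code{\link{thresholdProportional}}.
#' @return A \linkS4class{StaticNetwork}.
#' @export
staticNetwork <- function(ts, density, rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  stopifnot(is(ts, "RoiTimeSeries"))
  r <- stats::cor(ts@data)
  new("StaticNetwork",
      adjacency = thresholdProportional(r, density, rankBy),
      density = density)
}
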