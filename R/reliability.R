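#' Intraclass correlation ICC(3,1)
#'
#' Single-measure intraclass correlation from the two-way mixed model with
#' subjects as a random effect and scan session as a fixed effect:
#' ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS), where BMS is the
#' between-subjects mean square and EMS the residual mean square after the
#' scan main effect has been removed. Because the session effect is
#' partialled out, adding a distinct constant to each scan column leaves
#' the value unchanged (consistency, not absolute agreement).
#'
#' @param panel numeric matrix, n subjects (rows) x k scans (columns),
#'   no missing cells.
#' @return ICC(3,1) as a single number; NaN with a warning when the panel
#'   is perfectly constant (BMS = EMS = 0).
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(40), 10, 4) + rnorm(10)  # subject effect
#' icc31(y)
#' @export
icc31 <- function(panel) {
  panel <- as.matrix(panel)
  n <- nrow(panel)
  k <- ncol(panel)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 scans")
  if (anyNA(panel)) {
    bad <- which(is.na(panel), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell: subject %d, scan %d (no imputation)",
                 bad[1L], bad[2L]))
  }
  grand <- mean(panel)
  rowM <- rowMeans(panel)
  colM <- colMeans(panel)
  ssSubj <- k * sum((rowM - grand)^2)
  ssScan <- n * sum((colM - grand)^2)
  ssTot <- sum((panel - grand)^2)
  ssErr <- ssTot - ssSubj - ssScan
  bms <- ssSubj / (n - 1)
  ems <- ssErr / ((n - 1) * (k - 1))
  if (bms == 0 && ems == 0) {
    warning("all panel values identical: ICC undefined")
    return(NaN)
  }
  (bms - ems) / (bms + (k - 1) * ems)
}

#' F-distribution confidence interval for ICC(3,1)
#'
#' The standard interval based on F = BMS/EMS with (n-1) and (n-1)(k-1)
#' degrees of freedom.
#'
#' @param panel subjects x scans matrix as in \code{\link{icc31}}.
#' @param level confidence level, default 0.95.
#' @return named numeric vector with elements \code{icc}, \code{lower},
#'   \code{upper}.
#' @export
icc31ConfInt <- function(panel, level = 0.95) {
  panel <- as.matrix(panel)
  n <- nrow(panel)
  k <- ncol(panel)
  icc <- icc31(panel)
  grand <- mean(panel)
  rowM <- rowMeans(panel)
  colM <- colMeans(panel)
  bms <- k * sum((rowM - grand)^2) / (n - 1)
  ems <- (sum((panel - grand)^2) - k * sum((rowM - grand)^2) -
            n * sum((colM - grand)^2)) / ((n - 1) * (k - 1))
  fObs <- bms / ems
  alpha <- 1 - level
  fl <- fObs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- fObs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  c(icc = icc,
    lower = (fl - 1) / (fl + k - 1),
    upper = (fu - 1) / (fu + k - 1))
}

#' Qualitative reliability classification
#'
#' Bins an overall ICC into poor (< 0.4), moderate ([0.4, 0.6)),
#' good ([0.6, 0.75]) or excellent (> 0.75). The printed criterion leaves
#' exactly 0.75 unassigned; it is mapped to good (conservative,
#' measure-zero boundary). NaN maps to "undefined".
#'
#' @param value a finite ICC value (or NaN).
#' @return character scalar.
#' @examples
#' classifyIcc(0.43)   # "moderate"
#' classifyIcc(-0.1)   # "poor"
#' @export
classifyIcc <- function(value) {
  stopifnot(length(value) == 1L)
  if (is.nan(value) || is.na(value)) return("undefined")
  if (value < 0.4) "poor"
  else if (value < 0.6) "moderate"
  else if (value <= 0.75) "good"
  else "excellent"
}

# metric table (run level) -> subjects x runs panel for one
# (scope, metric, density) cell; errors on missing cells
.metricPanel <- function(metrics, scope, metric, density, subjects, runIds) {
  sel <- metrics$scope == scope & metrics$metric == metric &
    abs(metrics$density - density) < 1e-12
  sub <- metrics[sel, , drop = FALSE]
  panel <- matrix(NA_real_, length(subjects), length(runIds),
                  dimnames = list(subjects, runIds))
  idx <- cbind(match(sub$subject, subjects), match(sub$run, runIds))
  ok <- stats::complete.cases(idx)
  panel[idx[ok, , drop = FALSE]] <- sub$value[ok]
  if (anyNA(panel)) {
    miss <- which(is.na(panel), arr.ind = TRUE)
    lab <- paste(subjects[miss[, 1L]], runIds[miss[, 2L]], sep = "/",
                 collapse = ", ")
    stop(sprintf("unbalanced panel for %s %s at density %g; missing: %s",
                 metric, scope, density, lab))
  }
  panel
}

#' Test-retest reliability table
#'
#' For every metric and scope in a run-level metric table, computes
#' ICC(3,1) across the cohort's runs at every density, then the overall
#' (density-averaged) ICC, its SD across densities, and the qualitative
#' reliability class of the overall value.
#'
#' @param metrics run-level metric table (one record per subject, run,
#'   density, scope, metric).
#' @param coh a \linkS4class{Cohort}; its run count k must be >= 2.
#' @param scopes optional character vector restricting the scopes analysed
#'   (default: all scopes present).
#' @return list of \linkS4class{IccResult}, one per (metric, scope).
#' @seealso \code{\link{iccSummaryTable}} to flatten the results.
#' @export
iccTable <- function(metrics, coh, scopes = NULL) {
  stopifnot(is(coh, "Cohort"))
  if (nRuns(coh) < 2L) stop("reliability needs at least 2 runs per subject")
  subjects <- as.character(subjectTable(coh)$subjectId)
  runIds <- vapply(runsOf(coh, subjects[1L]), runId, character(1L))
  combos <- unique(metrics[, c("metric", "scope")])
  if (!is.null(scopes)) {
    combos <- combos[combos$scope %in% scopes, , drop = FALSE]
  }
  out <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    met <- combos$metric[r]
    sc <- combos$scope[r]
    densities <- sort(unique(metrics$density[metrics$metric == met &
                                               metrics$scope == sc]))
    per <- vapply(densities, function(d) {
      icc31(.metricPanel(metrics, sc, met, d, subjects, runIds))
    }, numeric(1L))
    names(per) <- formatC(densities, format = "g")
    overall <- mean(per)
    out[[r]] <- new("IccResult", scope = sc, metricName = met,
                    perDensity = per,
                    overallIcc = overall,
                    overallSd = if (length(per) > 1L) stats::sd(per) else 0,
                    reliabilityClass = classifyIcc(overall))
  }
  out
}

#' Flatten a list of IccResult into a data.frame
#'
#' @param results list returned by \code{\link{iccTable}}.
#' @return data.frame with columns metric, scope, overallIcc, overallSd,
#'   reliabilityClass.
#' @export
iccSummaryTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(metric = r@metricName, scope = r@scope,
               overallIcc = r@overallIcc, overallSd = r@overallSd,
               reliabilityClass = r@reliabilityClass,
               stringsAsFactors = FALSE)
  }))
}
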