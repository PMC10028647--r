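#' Sex and age effects on run-averaged network metrics
#'
#' Group analyses follow a fixed recipe: metrics are first averaged over a
#' subject's runs, the sex contrast is the between-subject stratum of a
#' repeated-measures ANCOVA with density as the within-subject factor
#' (computed exactly on each subject's density mean), and the age
#' association is a partial Spearman correlation of the density-averaged
#' metric with age, adjusted for sex, education and head motion. P values
#' are Bonferroni-corrected within declared families.
#'
#' @name group_stats
NULL

#' Average a metric table over runs
#'
#' Collapses run-level records to one record per (subject, density, scope,
#' metric) by the unweighted mean over runs; the run column is set to
#' \code{"mean-of-runs"}. Errors if runs are unbalanced across subjects.
#'
#' @param metrics run-level metric table.
#' @return metric table with one record per subject/density/scope/metric.
#' @export
averageRuns <- function(metrics) {
  counts <- table(metrics$subject)
  if (length(unique(counts)) > 1L) {
    stop("unbalanced runs: subjects differ in record counts (missing run?)")
  }
  agg <- stats::aggregate(
    value ~ subject + density + scope + metric, data = metrics, FUN = mean)
  agg$run <- "mean-of-runs"
  agg[, c("subject", "run", "density", "scope", "metric", "value")]
}

# density-mean per subject for one scope/metric, joined with covariates
.subjectDensityMeans <- function(metrics, coh, scope, metric) {
  sel <- metrics$scope == scope & metrics$metric == metric
  if (!any(sel)) stop(sprintf("no records for metric %s at scope %s",
                              metric, scope))
  sub <- metrics[sel, , drop = FALSE]
  m <- stats::aggregate(value ~ subject, data = sub, FUN = mean)
  s <- subjectTable(coh)
  merged <- merge(s, m, by.x = "subjectId", by.y = "subject")
  if (nrow(merged) != nrow(s)) stop("metric table does not cover the cohort")
  merged
}

# drop constant covariates; error on collinear ones
.covariateMatrix <- function(df, covariates) {
  keep <- covariates[vapply(covariates,
                            function(cv) stats::var(df[[cv]]) > 0,
                            logical(1L))]
  if (length(keep) >= 2L) {
    x <- as.matrix(df[, keep, drop = FALSE])
    if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
      stop(sprintf("collinear covariates among: %s",
                   paste(keep, collapse = ", ")))
    }
  }
  keep
}

#' Sex contrast on a run-averaged metric
#'
#' Tests the between-subject sex effect of the repeated-measures ANCOVA in
#' which density is the within-subject factor. In a balanced design the
#' between-subject stratum is carried entirely by each subject's mean over
#' the density levels, so the test is the F test of sex in the linear model
#' \code{densityMean ~ sex + age + education + meanFd}. Constant covariates
#' are dropped; the reported direction is the sign of the adjusted
#' (female - male) coefficient.
#'
#' @param metrics run-averaged metric table (see \code{\link{averageRuns}}).
#' @param coh a \linkS4class{Cohort} with at least 2 subjects per sex.
#' @param scope scope label, e.g. \code{"global"} or
#'   \code{"subnetwork:default-mode"}.
#' @param metric metric name, default \code{"temporal_clustering"}.
#' @param nTests Bonferroni family size used for the corrected p value.
#' @return one-row data.frame: scope, metric, F, pUncorrected, pCorrected,
#'   direction (sign of female - male), nTests.
#' @export
sexContrast <- function(metrics, coh, scope = "global",
                        metric = "temporal_clustering", nTests = 1L) {
  df <- .subjectDensityMeans(metrics, coh, scope, metric)
  if (any(table(df$sex) < 2L)) {
    stop("need at least 2 subjects of each sex")
  }
  covs <- .covariateMatrix(df, c("age", "education", "meanFd"))
  rhs <- paste(c("sex", covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = df)
  fit0 <- stats::update(fit, . ~ . - sex)
  an <- stats::anova(fit0, fit)
  fVal <- an$F[2L]
  pVal <- an$`Pr(>F)`[2L]
  data.frame(scope = scope, metric = metric, F = fVal,
             pUncorrected = pVal,
             pCorrected = bonferroni(pVal, nTests),
             direction = sign(stats::coef(fit)[["sexfemale"]]),
             nTests = as.integer(nTests),
             stringsAsFactors = FALSE)
}

#' Sex-by-age interaction screen
#'
#' Adds a sex x age term to the between-subjects model and returns its
#' corrected p value. Intended as a pre-check before interpreting separate
#' sex and age effects; a significant interaction is reported with a
#' warning, not an error.
#'
#' @inheritParams sexContrast
#' @return one-row data.frame: scope, metric, F, pUncorrected, pCorrected,
#'   nTests.
#' @export
interactionScreen <- function(metrics, coh, scope = "global",
                              metric = "temporal_clustering", nTests = 1L) {
  df <- .subjectDensityMeans(metrics, coh, scope, metric)
  if (any(table(df$sex) < 2L)) stop("need at least 2 subjects of each sex")
  covs <- setdiff(.covariateMatrix(df, c("age", "education", "meanFd")), "age")
  rhs <- paste(c("sex", "age", "sex:age", covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = df)
  fit0 <- stats::update(fit, . ~ . - sex:age)
  an <- stats::anova(fit0, fit)
  fVal <- an$F[2L]
  pVal <- an$`Pr(>F)`[2L]
  pC <- bonferroni(pVal, nTests)
  if (is.finite(pC) && pC < 0.05) {
    warning(sprintf("significant sex-by-age interaction at scope %s (corrected p = %.3g)",
                    scope, pC))
  }
  data.frame(scope = scope, metric = metric, F = fVal,
             pUncorrected = pVal, pCorrected = pC,
             nTests = as.integer(nTests), stringsAsFactors = FALSE)
}

# mid-rank transform
.midRank <- function(x) rank(x, ties.method = "average")

#' Partial Spearman correlation
#'
#' Rank-transforms every variable (mid-ranks for ties), residualizes the
#' ranked outcome and the ranked predictor on the ranked covariates by
#' least squares, and correlates the residuals. Degenerate (constant)
#' covariates are dropped, so with no informative covariates the value
#' reduces to the plain Spearman rho. The p value uses the t
#' approximation with n - 2 - q degrees of freedom (q = covariates kept).
#'
#' @param x,y numeric vectors.
#' @param z optional data.frame/matrix of covariates (may be NULL).
#' @return named numeric vector: rho, p, df.
#' @export
partialSpearman <- function(x, y, z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  rx <- .midRank(x)
  ry <- .midRank(y)
  q <- 0L
  if (!is.null(z)) {
    z <- as.data.frame(z)
    keep <- vapply(z, function(v) stats::var(as.numeric(v)) > 0, logical(1L))
    z <- z[, keep, drop = FALSE]
    q <- ncol(z)
    if (q > 0L) {
      rz <- vapply(z, function(v) .midRank(as.numeric(v)), numeric(n))
      rx <- stats::lm.fit(cbind(1, rz), rx)$residuals
      ry <- stats::lm.fit(cbind(1, rz), ry)$residuals
    }
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - q
  tStat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tStat), df)
  c(rho = rho, p = p, df = df)
}

#' Age association of a run-averaged metric
#'
#' Averages the metric over the density grid per subject, then computes the
#' partial Spearman correlation with age adjusted for sex, education and
#' head motion.
#'
#' @inheritParams sexContrast
#' @return one-row data.frame: scope, metric, rho, pUncorrected,
#'   pCorrected, nTests.
#' @export
ageCorrelation <- function(metrics, coh, scope = "global",
                           metric = "temporal_clustering", nTests = 1L) {
  df <- .subjectDensityMeans(metrics, coh, scope, metric)
  if (stats::var(df$age) == 0) stop("age is constant in this cohort")
  z <- data.frame(sex = as.numeric(df$sex), education = df$education,
                  meanFd = df$meanFd)
  ps <- partialSpearman(df$age, df$value, z)
  data.frame(scope = scope, metric = metric, rho = ps[["rho"]],
             pUncorrected = ps[["p"]],
             pCorrected = bonferroni(ps[["p"]], nTests),
             nTests = as.integer(nTests), stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each p value by the family size and caps at 1. The family
#' size follows the study design, e.g. 2 tests at the global level and
#' 2 x 9 = 18 at the subnetwork level.
#'
#' @param p numeric vector of p values in [0, 1].
#' @param nTests family size; must be at least \code{length(p)}.
#' @return corrected p values.
#' @examples
#' bonferroni(0.01, 18)  # 0.18
#' @export
bonferroni <- function(p, nTests) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  if (nTests < length(p)) {
    stop("nTests must be at least the number of p values in the family")
  }
  pmin(1, p * nTests)
}
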