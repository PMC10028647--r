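#' Synthetic cohort specification
#'
#' Constructs a \linkS4class{SynthSpec} with defaults chosen to emulate a
#' small resting-state test-retest study: 40 subjects with 4 runs of 300
#' timepoints at TR = 0.72 s over 20 nodes grouped into the nine canonical
#' subnetworks. Temporal persistence is controlled by the mean regime dwell
#' time (in timepoints); sex, age, a subject random effect and run noise
#' shift the per-run dwell additively. Ages are uniform on 22-37 years.
#'
#' @param nSubjects,kRuns,nNodes,tPoints,trSeconds cohort geometry.
#' @param subnetworkSizes integer vector of nodes per subnetwork; its names
#'   (default \code{\link{defaultSubnetworks}}) define the subnetwork set.
#' @param baseDwell mean regime dwell time, timepoints.
#' @param sexEffect additive dwell shift for females, timepoints.
#' @param ageSlope dwell change per year of age (centred).
#' @param ageRange \code{c(lo, hi)} years for the uniform age draw.
#' @param sigmaSubject SD of the subject-level random dwell effect.
#' @param sigmaRun SD of the run-level dwell noise.
#' @param noiseSd observation noise SD.
#' @param regimeRho within-community correlation of a regime's signal.
#' @param nCommunities latent communities per regime.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(nSubjects = 40L, kRuns = 4L, nNodes = 20L,
                      subnetworkSizes = NULL, tPoints = 300L,
                      trSeconds = 0.72, baseDwell = 25, sexEffect = 20,
                      ageSlope = 1, ageRange = c(22, 37),
                      sigmaSubject = 12, sigmaRun = 5, noiseSd = 0.6,
                      regimeRho = 0.85, nCommunities = 3L, seed = 1L) {
  if (is.null(subnetworkSizes)) {
    base <- rep(nNodes %/% 9L, 9L)
    extra <- nNodes %% 9L
    if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    if (any(base < 1L)) stop("nNodes too small for 9 subnetworks")
    subnetworkSizes <- stats::setNames(base, defaultSubnetworks())
  }
  if (is.null(names(subnetworkSizes))) {
    names(subnetworkSizes) <- defaultSubnetworks()[seq_along(subnetworkSizes)]
  }
  new("SynthSpec",
      nSubjects = as.integer(nSubjects), kRuns = as.integer(kRuns),
      nNodes = as.integer(nNodes),
      subnetworkSizes = stats::setNames(as.integer(subnetworkSizes),
                                        names(subnetworkSizes)),
      tPoints = as.integer(tPoints), trSeconds = as.numeric(trSeconds),
      baseDwell = as.numeric(baseDwell), sexEffect = as.numeric(sexEffect),
      ageSlope = as.numeric(ageSlope), ageRange = as.numeric(ageRange),
      sigmaSubject = as.numeric(sigmaSubject),
      sigmaRun = as.numeric(sigmaRun), noiseSd = as.numeric(noiseSd),
      regimeRho = as.numeric(regimeRho),
      nCommunities = as.integer(nCommunities), seed = as.integer(seed))
}

# parcellation implied by a SynthSpec
.synthParcellation <- function(spec) {
  subnet <- rep(names(spec@subnetworkSizes), spec@subnetworkSizes)
  ids <- paste0("n", seq_len(spec@nNodes))
  parcellation(ids, subnet, subnetworkSet = names(spec@subnetworkSizes))
}

# one run of the regime-switching Gaussian model.
# lambda: mean dwell (timepoints, >= 2 after clipping upstream).
# Returns the T x N signal matrix.
.simulateRun <- function(lambda, spec, parc) {
  tP <- spec@tPoints
  n <- spec@nNodes
  subnetIdx <- match(parc@subnetwork, parc@subnetworkSet)
  nSub <- length(parc@subnetworkSet)
  # regime durations: geometric with mean lambda (support 1, 2, ...)
  p <- 1 / lambda
  durations <- integer(0L)
  total <- 0L
  while (total < tP) {
    d <- 1L + stats::rgeom(1L, p)
    durations <- c(durations, d)
    total <- total + d
  }
  nReg <- length(durations)
  regimeOfT <- rep.int(seq_len(nReg), durations)[seq_len(tP)]
  # each regime shuffles subnetworks into latent communities
  commOfSub <- matrix(sample.int(spec@nCommunities, nReg * nSub, replace = TRUE),
                      nReg, nSub)
  commOfNode <- commOfSub[, subnetIdx, drop = FALSE]  # nReg x N
  # shared community factors per timepoint
  fac <- matrix(stats::rnorm(tP * spec@nCommunities), tP, spec@nCommunities)
  commIdx <- commOfNode[regimeOfT, , drop = FALSE]    # T x N
  shared <- matrix(fac[cbind(rep(seq_len(tP), n), as.vector(commIdx))], tP, n)
  rho <- spec@regimeRho
  x <- sqrt(rho) * shared +
    sqrt(1 - rho) * matrix(stats::rnorm(tP * n), tP, n) +
    spec@noiseSd * matrix(stats::rnorm(tP * n), tP, n)
  colnames(x) <- parc@nodeIds
  x
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject sex (Bernoulli 0.5), age (uniform), education
#' (Gaussian) and mean framewise displacement (log-normal), then per run a
#' latent dwell time
#' \deqn{\lambda = baseDwell + sexEffect \cdot 1[female] +
#'   ageSlope (age - \bar{age}) + b_{subject} + e_{run}}
#' with \eqn{b_{subject} \sim N(0, \sigma_{subject}^2)} shared across the
#' subject's runs and \eqn{e_{run} \sim N(0, \sigma_{run}^2)}, clipped at
#' 2 timepoints. Each run is a regime-switching Gaussian time series:
#' regime durations are geometric with mean \eqn{\lambda}, and each regime
#' reassigns the subnetworks to latent communities whose members share a
#' common signal. Deterministic given \code{spec@seed}.
#'
#' If \code{tPoints} is smaller than twice the intended downstream window
#' width the generator warns (too few windows for temporal metrics) but
#' still simulates.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param dir optional directory; when given, per-run time-series TSVs, the
#'   parcellation TSV, the cohort manifest CSV and a JSON ground-truth
#'   sidecar are written there.
#' @param intendedWindowWidth window width (TRs) the caller plans to use;
#'   only used for the feasibility warning. Default 30.
#' @return list with elements \code{cohort} (\linkS4class{Cohort}),
#'   \code{parcellation} (\linkS4class{Parcellation}) and \code{truth}
#'   (data.frame: subjectId, runId, lambda, bSubject).
#' @export
simulateCohort <- function(spec, dir = NULL, intendedWindowWidth = 30L) {
  stopifnot(is(spec, "SynthSpec"))
  if (spec@tPoints < 2L * intendedWindowWidth) {
    warning(sprintf("tPoints (%d) < 2 x window width (%d): few or no windows downstream",
                    spec@tPoints, intendedWindowWidth))
  }
  parc <- .synthParcellation(spec)
  withSeed(spec@seed, {
    n <- spec@nSubjects
    ids <- sprintf("sub%03d", seq_len(n))
    sex <- factor(ifelse(stats::runif(n) < 0.5, "female", "male"),
                  levels = c("male", "female"))
    age <- stats::runif(n, spec@ageRange[1L], spec@ageRange[2L])
    education <- stats::rnorm(n, 14, 2)
    meanFd <- stats::rlnorm(n, log(0.15), 0.3)
    bSubject <- stats::rnorm(n, 0, spec@sigmaSubject)
    ageCentered <- age - mean(age)
    subjects <- data.frame(subjectId = ids, sex = sex, age = age,
                           education = education, meanFd = meanFd,
                           stringsAsFactors = FALSE)
    runs <- vector("list", n)
    names(runs) <- ids
    truth <- vector("list", n)
    for (s in seq_len(n)) {
      runList <- vector("list", spec@kRuns)
      lam <- numeric(spec@kRuns)
      for (r in seq_len(spec@kRuns)) {
        lambda <- spec@baseDwell +
          spec@sexEffect * (sex[s] == "female") +
          spec@ageSlope * ageCentered[s] +
          bSubject[s] + stats::rnorm(1L, 0, spec@sigmaRun)
        lambda <- max(lambda, 2)
        lam[r] <- lambda
        x <- .simulateRun(lambda, spec, parc)
        runList[[r]] <- roiTimeSeries(x, spec@trSeconds,
                                      subjectId = ids[s],
                                      runId = sprintf("run%d", r))
      }
      runs[[s]] <- runList
      truth[[s]] <- data.frame(subjectId = ids[s],
                               runId = sprintf("run%d", seq_len(spec@kRuns)),
                               lambda = lam, bSubject = bSubject[s],
                               stringsAsFactors = FALSE)
    }
    coh <- cohort(subjects, runs)
    truthDf <- do.call(rbind, truth)
    if (!is.null(dir)) {
      .writeCohortFiles(coh, parc, truthDf, spec, dir)
    }
    list(cohort = coh, parcellation = parc, truth = truthDf)
  })
}

#' Simulate a subject-by-scan metric panel
#'
#' Draws y_sj = mu + b_s + e_sj with b_s ~ N(0, sigmaB^2) and
#' e_sj ~ N(0, sigmaW^2): the two-variance-component model under which the
#' population ICC(3,1) is sigmaB^2 / (sigmaB^2 + sigmaW^2). Used to
#' validate ICC recovery independently of any network computation.
#'
#' @param nSubjects number of subjects (rows).
#' @param k scans per subject (columns), k >= 2.
#' @param sigmaB between-subject SD.
#' @param sigmaW within-subject SD.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return nSubjects x k numeric matrix.
#' @export
simulateMetricPanel <- function(nSubjects, k, sigmaB, sigmaW, mu = 0,
                                seed = 1L) {
  stopifnot(k >= 2L, sigmaB >= 0, sigmaW >= 0)
  withSeed(seed, {
    b <- stats::rnorm(nSubjects, 0, sigmaB)
    mu + matrix(b, nSubjects, k) +
      matrix(stats::rnorm(nSubjects * k, 0, sigmaW), nSubjects, k)
  })
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
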