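# Independent oracles and small fixture builders. Oracles deliberately use
# literal loops / textbook formulas, never the package's vectorized paths.

# literal triple-loop temporal clustering: loops over t, i, j
bruteTemporalClustering <- function(arr) {
  n <- dim(arr)[1L]
  w <- dim(arr)[3L]
  ci <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq_len(w - 1L)) {
      num <- 0; d1 <- 0; d2 <- 0
      for (j in seq_len(n)) {
        num <- num + arr[i, j, t] * arr[i, j, t + 1L]
        d1 <- d1 + arr[i, j, t]
        d2 <- d2 + arr[i, j, t + 1L]
      }
      if (d1 > 0 && d2 > 0) acc <- acc + num / sqrt(d1 * d2)
    }
    ci[i] <- acc / (w - 1L)
  }
  ci
}

# BFS shortest-path distances on a binary adjacency matrix
bfsDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nxt <- integer(0L)
      for (v in frontier) {
        for (u in which(adj[v, ] == 1L)) {
          if (d[s, u] > lev) { d[s, u] <- lev; nxt <- c(nxt, u) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

bruteLocalEfficiency <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) next
    d <- bfsDistances(adj[nb, nb, drop = FALSE])
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b && is.finite(d[a, b])) s <- s + 1 / d[a, b]
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

bruteClustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) next
    tri <- 0
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      tri <- tri + adj[nb[a], nb[b]]
    }
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

# ICC(3,1) through R's own two-way ANOVA decomposition
aovIcc31 <- function(panel) {
  n <- nrow(panel); k <- ncol(panel)
  df <- data.frame(y = as.vector(panel),
                   subject = factor(rep(seq_len(n), k)),
                   scan = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subject + scan, data = df))[[1L]]
  bms <- tab["subject", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (k - 1) * ems)
}

# partial rank correlation via inversion of the rank correlation matrix
brutePartialSpearman <- function(x, y, z) {
  r <- apply(cbind(x, y, as.matrix(z)), 2L, rank)
  cm <- stats::cor(r)
  pm <- solve(cm)
  -pm[1L, 2L] / sqrt(pm[1L, 1L] * pm[2L, 2L])
}

# random binary symmetric zero-diagonal adjacency stack wrapped as a
# MultilayerNetwork-compatible array (edge counts vary; used with the
# brute-force oracle only)
randomAdjStack <- function(n, w, p = 0.4) {
  arr <- array(0L, dim = c(n, n, w))
  for (t in seq_len(w)) {
    a <- matrix(0L, n, n)
    up <- which(upper.tri(a))
    a[up] <- as.integer(runif(length(up)) < p)
    a <- a + t(a)
    arr[, , t] <- a
  }
  arr
}

# adjacency from an edge list on n nodes
adjFromEdges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1L], e[2L]] <- 1L; a[e[2L], e[1L]] <- 1L }
  a
}

# small parcellation over two custom subnetworks
tinyParcellation <- function(n = 4L) {
  parcellation(paste0("n", seq_len(n)),
               rep(c("A", "B"), length.out = n),
               subnetworkSet = c("A", "B"))
}

# deterministic RoiTimeSeries fixture
tinyTs <- function(tP = 40L, n = 5L, seed = 1L, tr = 0.72) {
  withSeed(seed, roiTimeSeries(matrix(rnorm(tP * n), tP, n), tr))
}

# metric table with injected values for a 2-subject, 2-run cohort shape
injectedMetricTable <- function(values, subjects, runs, density = 0.1,
                                scope = "global",
                                metric = "temporal_clustering") {
  grid <- expand.grid(run = runs, subject = subjects,
                      stringsAsFactors = FALSE)
  data.frame(subject = grid$subject, run = grid$run, density = density,
             scope = scope, metric = metric, value = values,
             stringsAsFactors = FALSE)
}

# minimal cohort with given per-subject covariates and no real runs needed
# by the group-stats path (runs only used for k); attach tiny runs
syntheticStatCohort <- function(subjects, kRuns = 2L) {
  runs <- lapply(seq_len(nrow(subjects)), function(i) {
    lapply(seq_len(kRuns), function(r) {
      withSeed(i * 100L + r,
               roiTimeSeries(matrix(rnorm(40), 10, 4), 0.72,
                             subjectId = subjects$subjectId[i],
                             runId = sprintf("run%d", r)))
    })
  })
  names(runs) <- subjects$subjectId
  cohort(subjects, runs)
}
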