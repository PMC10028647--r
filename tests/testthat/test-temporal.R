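test_that("identical layers with positive degrees give C_i = 1", {
  a <- adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4)))
  arr <- array(a, dim = c(4, 4, 5))
  expect_equal(unname(nodalTemporalClustering(arr)), rep(1, 4))
})

test_that("two-layer toy matches the hand-evaluated overlap formula", {
  l1 <- adjFromEdges(3, list(c(1, 2)))
  l2 <- adjFromEdges(3, list(c(1, 2), c(1, 3)))
  arr <- array(c(l1, l2), dim = c(3, 3, 2))
  ci <- nodalTemporalClustering(arr)
  # node 1: overlap 1 / sqrt(1 * 2); node 2: 1 / sqrt(1 * 1); node 3 isolated
  expect_equal(unname(ci), c(1 / sqrt(2), 1, 0), tolerance = 1e-15)
})

test_that("vectorized coefficients equal the literal triple-loop oracle", {
  withSeed(101, {
    for (rep in 1:60) {
      n <- sample(3:10, 1L)
      w <- sample(2:8, 1L)
      arr <- randomAdjStack(n, w, p = runif(1, 0.1, 0.8))
      expect_equal(unname(nodalTemporalClustering(arr)),
                   bruteTemporalClustering(arr), tolerance = 1e-12)
    }
  })
})

test_that("coefficients are bounded in [0,1] and time-reversal invariant", {
  withSeed(17, {
    for (rep in 1:30) {
      arr <- randomAdjStack(sample(4:9, 1L), sample(3:7, 1L))
      ci <- nodalTemporalClustering(arr)
      expect_true(all(ci >= 0 & ci <= 1 + 1e-12))
      rev <- arr[, , dim(arr)[3L]:1, drop = FALSE]
      expect_equal(ci, nodalTemporalClustering(rev), tolerance = 1e-12)
    }
  })
})

test_that("C_i = 1 exactly when the neighbour set is constant and nonempty", {
  withSeed(23, {
    for (rep in 1:20) {
      n <- 6L; w <- 4L
      arr <- randomAdjStack(n, w, 0.5)
      ci <- nodalTemporalClustering(arr)
      constantNbrs <- vapply(seq_len(n), function(i) {
        nb <- apply(arr[i, , , drop = FALSE], 3L, identity)
        all(vapply(2:w, function(t) identical(nb[, t], nb[, 1L]), logical(1L))) &&
          sum(nb[, 1L]) > 0
      }, logical(1L))
      expect_equal(ci == 1, constantNbrs)
    }
  })
})

test_that("single-layer networks are rejected", {
  arr <- randomAdjStack(4, 1)
  expect_error(nodalTemporalClustering(arr), "at least 2 layers")
})

test_that("aggregation takes unweighted means at both scopes", {
  parc <- tinyParcellation(4)  # groups A = {1,3}, B = {2,4}
  res <- aggregateTemporalClustering(c(1, 0, 0.5, 0.5), parc)
  expect_equal(res@globalValue, 0.5)
  expect_equal(unname(res@subnetworkValues), c(0.75, 0.25))
  resC <- aggregateTemporalClustering(rep(0.3, 4), parc)
  expect_equal(resC@globalValue, 0.3)
  expect_equal(unname(resC@subnetworkValues), c(0.3, 0.3))
  expect_error(aggregateTemporalClustering(c(1, 2), parc), "does not match")
})

test_that("node permutation with matching parcellation leaves summaries fixed", {
  ts <- tinyTs(60, 6, seed = 5)
  parc <- parcellation(colnames(signalMatrix(ts)),
                       rep(c("A", "B", "C"), each = 2),
                       subnetworkSet = c("A", "B", "C"))
  ws <- windowSpec(20, 10)
  tab <- runTemporalPipeline(ts, ws, c(0.2, 0.4), parc)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  tsP <- roiTimeSeries(signalMatrix(ts)[, perm], trSeconds(ts))
  parcP <- parcellation(nodeIds(parc)[perm], subnetworks(parc)[perm],
                        subnetworkSet = c("A", "B", "C"))
  tabP <- runTemporalPipeline(tsP, ws, c(0.2, 0.4), parcP)
  for (sc in c("global", "subnetwork:A", "subnetwork:B", "subnetwork:C",
               "node:n4", "node:n1")) {
    expect_equal(tab$value[tab$scope == sc], tabP$value[tabP$scope == sc],
                 tolerance = 1e-12)
  }
})

test_that("the run pipeline emits the full record grid deterministically", {
  ts <- tinyTs(60, 6, seed = 8)
  parc <- parcellation(colnames(signalMatrix(ts)),
                       rep(c("A", "B", "C"), each = 2),
                       subnetworkSet = c("A", "B", "C"))
  dens <- c(0.1, 0.2, 0.3)
  tab <- runTemporalPipeline(ts, windowSpec(20, 10), dens, parc)
  expect_equal(nrow(tab), length(dens) * (1 + 3 + 6))
  expect_setequal(unique(tab$scope),
                  c("global", paste0("subnetwork:", c("A", "B", "C")),
                    paste0("node:", nodeIds(parc))))
  expect_true(all(tab$value >= 0 & tab$value <= 1))
  # global record equals mean of nodal records at each density
  for (d in dens) {
    sub <- tab[abs(tab$density - d) < 1e-12, ]
    expect_equal(sub$value[sub$scope == "global"],
                 mean(sub$value[startsWith(sub$scope, "node:")]),
                 tolerance = 1e-12)
  }
  expect_identical(tab, runTemporalPipeline(ts, windowSpec(20, 10), dens, parc))
})

test_that("the rank-position sweep agrees with the materialized-stack path", {
  ts <- tinyTs(80, 7, seed = 12)
  ws <- windowSpec(20, 10)
  dens <- defaultDensityGrid()
  nets <- suppressWarnings(buildMultilayer(ts, ws, dens))
  slow <- vapply(nets, function(nt) mean(nodalTemporalClustering(nt)),
                 numeric(1L))
  stack <- windowCorrelations(ts, ws)
  fast <- suppressWarnings(
    rowMeans(temponet:::.globalTemporalClusteringSweep(stack, dens, "signed")))
  expect_equal(unname(fast), unname(slow), tolerance = 1e-12)
})
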