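test_that("window planner reproduces the reference tiling arithmetic", {
  expect_equal(nrow(planWindows(1200, windowSpec(139, 8))), 133L)
  p1 <- planWindows(139, windowSpec(139, 8))
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$start, p1$end), c(0L, 139L))
  p2 <- planWindows(20, windowSpec(10, 5))
  expect_equal(p2$start, c(0L, 5L, 10L))
  expect_error(planWindows(100, windowSpec(139, 8)), "exceeds")
})

test_that("window count matches explicit enumeration for random geometries", {
  withSeed(42, {
    for (rep in 1:50) {
      tP <- sample(10:400, 1L)
      w <- sample(2:tP, 1L)
      s <- sample(1:30, 1L)
      plan <- planWindows(tP, windowSpec(w, s))
      # enumerate starts literally
      starts <- 0L
      while (utils::tail(starts, 1L) + s + w <= tP) {
        starts <- c(starts, utils::tail(starts, 1L) + s)
      }
      expect_equal(plan$start, starts)
      expect_equal(nrow(plan), floor((tP - w) / s) + 1L)
      expect_true(all(plan$end <= tP))
    }
  })
})

test_that("window correlations match the Pearson formula and its edge cases", {
  withSeed(7, {
    x <- rnorm(24)
    m <- cbind(a = x, b = 3 * x + 2, c = -x)  # affine and sign-flipped copies
    ts <- roiTimeSeries(m, 0.72)
    st <- windowCorrelations(ts, windowSpec(8, 4))
    expect_equal(nLayers(st), 5L)
    for (t in seq_len(5L)) {
      expect_equal(layers(st)[1, 2, t], 1)
      expect_equal(layers(st)[1, 3, t], -1)
    }
  })
  # 6-timepoint, 3-node toy against the raw product-moment formula
  toy <- matrix(c(1, 3, 2, 5, 4, 6,
                  2, 2, 4, 3, 6, 5,
                  6, 4, 5, 2, 3, 1), 6, 3)
  ts <- roiTimeSeries(toy, 1)
  st <- windowCorrelations(ts, windowSpec(6, 1))
  pearson <- function(u, v) {
    num <- sum((u - mean(u)) * (v - mean(v)))
    num / sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(layers(st)[i, j, 1], pearson(toy[, i], toy[, j]),
                 tolerance = 1e-15)
  }
  # constant node inside a window is reported by window and node
  bad <- roiTimeSeries(cbind(n1 = c(1, 1, 1, 1, 2, 3),
                             n2 = rnorm(6)), 1)
  expect_error(windowCorrelations(bad, windowSpec(4, 1)),
               "node n1 in window 1")
})

test_that("proportional thresholding keeps exactly the strongest edges", {
  r <- diag(4)
  vals <- c(0.9, -0.2, 0.5, 0.7, 0.1, 0.4)  # pairs (1,2)(1,3)(1,4)(2,3)(2,4)(3,4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  r[pairs] <- vals; r[pairs[, 2:1]] <- vals
  a <- thresholdProportional(r, 0.5)
  expect_equal(sum(a[upper.tri(a)]), 3L)
  expect_equal(a[1, 2] + a[2, 3] + a[1, 4], 3L)  # the three largest r
  # ranking by magnitude pulls in strong negatives
  r2 <- r; r2[1, 3] <- -0.95; r2[3, 1] <- -0.95
  aAbs <- thresholdProportional(r2, 0.25, rankBy = "absolute")
  expect_equal(sum(aAbs[upper.tri(aAbs)]), 2L)  # k = round(0.25 * 6)
  expect_equal(aAbs[1, 3], 1L)  # |-0.95| outranks 0.7
  expect_equal(aAbs[1, 2], 1L)
  # density 1 gives the complete graph
  full <- thresholdProportional(r, 1)
  expect_true(all(full[upper.tri(full)] == 1L))
  expect_true(all(diag(full) == 0L))
})

test_that("ties at the cutoff resolve to lexicographically first pairs", {
  r <- matrix(0.5, 4, 4); diag(r) <- 1
  a <- thresholdProportional(r, 0.5)
  expect_equal(a[1, 2], 1L)
  expect_equal(a[1, 3], 1L)
  expect_equal(a[1, 4], 1L)
  expect_equal(sum(a[upper.tri(a)]), 3L)
})

test_that("thresholding is rank-based: invariant to increasing transforms", {
  withSeed(11, {
    for (rep in 1:20) {
      n <- sample(5:12, 1L)
      r <- stats::cor(matrix(rnorm(40 * n), 40, n))
      d <- runif(1, 0.05, 0.9)
      a1 <- thresholdProportional(r, d)
      # strictly increasing transform of the correlation values
      a2 <- thresholdProportional(tanh(3 * r) + 0.1 * r, d)
      expect_identical(unname(a1), unname(a2))
    }
  })
})

test_that("layer edge counts are exact and nested across densities", {
  ts <- tinyTs(60, 8, seed = 3)
  nets <- buildMultilayer(ts, windowSpec(20, 10), densities = c(0.1, 0.3, 0.5))
  expect_length(nets, 3L)
  for (d in c(0.1, 0.3, 0.5)) {
    net <- nets[[formatC(d, format = "g")]]
    kExp <- round(d * 8 * 7 / 2)
    for (t in seq_len(nLayers(net))) {
      a <- layers(net)[, , t]
      expect_equal(sum(a[upper.tri(a)]), kExp)
      expect_identical(unname(a), unname(t(a)))
    }
  }
  # nesting: lower-density edge sets are subsets of higher-density ones
  for (t in seq_len(nLayers(nets[[1]]))) {
    expect_true(all(layers(nets[[1]])[, , t] <= layers(nets[[2]])[, , t]))
    expect_true(all(layers(nets[[2]])[, , t] <= layers(nets[[3]])[, , t]))
  }
})

test_that("the default sweep produces 50 networks and seconds convert", {
  expect_length(defaultDensityGrid(), 50L)
  ts <- tinyTs(50, 5, seed = 9)
  # with 10 node pairs the lowest densities legitimately retain no edges
  nets <- suppressWarnings(buildMultilayer(ts, windowSpec(25, 25)))
  expect_length(nets, 50L)
  expect_equal(unname(windowSeconds(windowSpec(139, 8), 0.72)),
               c(100.08, 5.76))
})

test_that("zero retained edges yields an empty layer with a warning", {
  r <- stats::cor(matrix(rnorm(100), 20, 5))
  expect_warning(a <- thresholdProportional(r, 0.01), "zero edges")
  expect_true(all(a == 0L))
})
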