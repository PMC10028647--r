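test_that("run averaging collapses to subject means and is order-invariant", {
  tab <- injectedMetricTable(c(0.2, 0.4, 0.6, 0.8), c("a", "b"),
                             c("run1", "run2"))
  avg <- averageRuns(tab)
  expect_equal(avg$value[avg$subject == "a"], 0.3)
  expect_equal(avg$value[avg$subject == "b"], 0.7)
  expect_true(all(avg$run == "mean-of-runs"))
  # permuting run record order changes nothing
  avg2 <- averageRuns(tab[c(3, 1, 4, 2), ])
  expect_equal(avg, avg2)
  # a single run is the identity on values
  one <- injectedMetricTable(c(0.2, 0.8), c("a", "b"), "run1")
  expect_equal(averageRuns(one)$value, c(0.2, 0.8))
  # missing run is an error
  expect_error(averageRuns(tab[-1L, ]), "unbalanced")
})

test_that("sex contrast reduces to the one-way ANOVA F under flat covariates", {
  subjects <- data.frame(subjectId = sprintf("s%d", 1:6),
                         sex = rep(c("male", "female"), each = 3),
                         age = 30, education = 14, meanFd = 0.15)
  coh <- syntheticStatCohort(subjects)
  vals <- c(1.1, 0.9, 1.0, 2.2, 1.8, 2.0)
  avg <- injectedMetricTable(vals, subjects$subjectId, "mean-of-runs")
  res <- sexContrast(avg, coh, nTests = 2)
  # hand-computed one-way ANOVA F
  g1 <- vals[1:3]; g2 <- vals[4:6]
  ssb <- 3 * ((mean(g1) - mean(vals))^2 + (mean(g2) - mean(vals))^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  fHand <- (ssb / 1) / (ssw / 4)
  expect_equal(res$F, fHand, tolerance = 1e-10)
  expect_equal(res$direction, 1)  # females higher
  expect_equal(res$pCorrected, min(1, res$pUncorrected * 2))
})

test_that("cloned groups give F near zero and p near one", {
  # the male and female member of each pair share metric and covariates,
  # so the adjusted sex difference is exactly zero
  subjects <- data.frame(subjectId = sprintf("s%02d", 1:12),
                         sex = rep(c("male", "female"), 6),
                         age = rep(c(24, 28, 32, 36, 26, 34), each = 2),
                         education = rep(c(12, 16, 13, 15, 14, 17), each = 2),
                         meanFd = rep(c(0.1, 0.2, 0.15, 0.12, 0.18, 0.11),
                                      each = 2))
  vals <- rep(c(0.3, 0.6, 0.7, 0.9, 0.4, 0.8), each = 2)
  coh <- syntheticStatCohort(subjects)
  avg <- injectedMetricTable(vals, subjects$subjectId, "mean-of-runs")
  res <- sexContrast(avg, coh, nTests = 1)
  expect_lt(res$F, 1e-10)
  expect_gt(res$pUncorrected, 0.999)
  resI <- suppressWarnings(interactionScreen(avg, coh, nTests = 1))
  expect_gt(resI$pUncorrected, 0.5)
})

test_that("the sex F statistic ignores affine rescaling of metric and covariates", {
  withSeed(71, {
    subjects <- data.frame(subjectId = sprintf("s%02d", 1:30),
                           sex = rep(c("male", "female"), 15),
                           age = runif(30, 22, 37),
                           education = rnorm(30, 14, 2),
                           meanFd = rlnorm(30, log(0.15), 0.3))
    coh <- syntheticStatCohort(subjects)
    vals <- runif(30, 0.3, 0.7)
    avg <- injectedMetricTable(vals, subjects$subjectId, "mean-of-runs")
    f1 <- sexContrast(avg, coh)$F
    avg2 <- avg; avg2$value <- 100 * avg2$value - 7
    subjects2 <- subjects
    subjects2$age <- subjects2$age / 10 + 3
    subjects2$meanFd <- subjects2$meanFd * 50
    coh2 <- syntheticStatCohort(subjects2)
    f2 <- sexContrast(avg2, coh2)$F
    expect_equal(f1, f2, tolerance = 1e-9)
  })
})

test_that("sex contrast type-I error sits at its nominal level", {
  # identical generating law for both sexes, metric-level simulation
  withSeed(404, {
    nSeeds <- 200
    rej <- logical(nSeeds)
    for (s in seq_len(nSeeds)) {
      subjects <- data.frame(subjectId = sprintf("s%03d", 1:200),
                             sex = rep(c("male", "female"), 100),
                             age = runif(200, 22, 37),
                             education = rnorm(200, 14, 2),
                             meanFd = rlnorm(200, log(0.15), 0.3))
      coh <- syntheticStatCohort(subjects, kRuns = 2L)
      avg <- injectedMetricTable(rnorm(200, 0.5, 0.05),
                                 subjects$subjectId, "mean-of-runs")
      rej[s] <- sexContrast(avg, coh)$pUncorrected < 0.05
    }
    expect_gt(mean(rej), 0.02)
    expect_lt(mean(rej), 0.08)
  })
})

test_that("partial Spearman matches the matrix-inversion oracle", {
  withSeed(91, {
    for (rep in 1:10) {
      n <- 8L
      x <- rnorm(n); y <- rnorm(n)
      z <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
      ps <- partialSpearman(x, y, z)
      expect_equal(ps[["rho"]], brutePartialSpearman(x, y, z),
                   tolerance = 1e-12)
    }
  })
})

test_that("partial Spearman is invariant to monotone transforms and reduces cleanly", {
  withSeed(92, {
    n <- 40L
    x <- rnorm(n); y <- x + rnorm(n)
    z <- data.frame(a = rnorm(n), b = rnorm(n))
    base <- partialSpearman(x, y, z)[["rho"]]
    warped <- partialSpearman(exp(2 * x), y^3 + 5 * y,
                              data.frame(a = exp(z$a), b = atan(z$b)))
    expect_equal(base, warped[["rho"]], tolerance = 1e-12)
    # constant covariates are dropped: plain Spearman
    flat <- partialSpearman(x, y, data.frame(a = rep(1, n), b = rep(2, n)))
    expect_equal(flat[["rho"]], cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(flat[["df"]], n - 2)
  })
})

test_that("age correlation finds a strong built-in age trend", {
  withSeed(93, {
    n <- 100L
    subjects <- data.frame(subjectId = sprintf("s%03d", 1:n),
                           sex = rep(c("male", "female"), n / 2),
                           age = runif(n, 22, 37),
                           education = rnorm(n, 14, 2),
                           meanFd = rlnorm(n, log(0.15), 0.3))
    coh <- syntheticStatCohort(subjects)
    vals <- 0.3 + 0.01 * subjects$age + rnorm(n, 0, 0.002)
    avg <- injectedMetricTable(vals, subjects$subjectId, "mean-of-runs")
    res <- ageCorrelation(avg, coh, nTests = 2)
    expect_gt(res$rho, 0.9)
    expect_lt(res$pCorrected, 0.001)
    expect_error(ageCorrelation(avg,
      syntheticStatCohort(transform(subjects, age = 30))), "constant")
  })
})

test_that("interaction screen flags a built-in sex-by-age slope difference", {
  withSeed(94, {
    n <- 200L
    subjects <- data.frame(subjectId = sprintf("s%03d", 1:n),
                           sex = rep(c("male", "female"), n / 2),
                           age = runif(n, 22, 37),
                           education = rnorm(n, 14, 2),
                           meanFd = rlnorm(n, log(0.15), 0.3))
    coh <- syntheticStatCohort(subjects)
    slope <- ifelse(subjects$sex == "female", 0.02, -0.02)
    vals <- 0.5 + slope * (subjects$age - 30) + rnorm(n, 0, 0.05)
    avg <- injectedMetricTable(vals, subjects$subjectId, "mean-of-runs")
    expect_warning(res <- interactionScreen(avg, coh, nTests = 1),
                   "interaction")
    expect_lt(res$pCorrected, 0.05)
  })
})

test_that("Bonferroni correction multiplies, caps, and validates", {
  expect_equal(bonferroni(0.01, 18), 0.18)
  expect_equal(bonferroni(0.2, 18), 1)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(c(0.001, 0.03), 2), c(0.002, 0.06))
  expect_error(bonferroni(1.2, 2), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2, 0.3), 2), "at least")
})

test_that("rank-deficient covariates are named, one-sex cohorts refused", {
  subjects <- data.frame(subjectId = sprintf("s%d", 1:10),
                         sex = rep(c("male", "female"), 5),
                         age = 1:10, education = 2 * (1:10) + 3,
                         meanFd = rep(0.2, 10))
  coh <- syntheticStatCohort(subjects)
  avg <- injectedMetricTable(runif(10), subjects$subjectId, "mean-of-runs")
  expect_error(sexContrast(avg, coh), "collinear")
  oneSex <- transform(subjects, sex = "male")
  expect_error(sexContrast(avg, syntheticStatCohort(oneSex)),
               "each sex")
})
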