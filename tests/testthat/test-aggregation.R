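test_that("level summaries match textbook two-pass formulas", {
  s1 <- summarizeLevel(5, "one")
  expect_equal(poolMean(s1), 5); expect_equal(poolVariance(s1), 0)
  expect_true(s1@degenerate)
  s2 <- summarizeLevel(c(1, 2, 3), "abc")
  expect_equal(poolMean(s2), 2); expect_equal(poolVariance(s2), 1)
  set.seed(71)
  v <- runif(25, -10, 10)
  s3 <- summarizeLevel(v)
  m <- sum(v) / 25
  expect_equal(poolMean(s3), m, tolerance = 1e-12)
  expect_equal(poolVariance(s3), sum((v - m)^2) / 24, tolerance = 1e-12)
  expect_error(summarizeLevel(numeric(0)), "empty")
})

test_that("count-weighted pooling equals a flat expansion oracle", {
  eq <- weightedMeanByCount(list(summarizeLevel(c(0, 0)),
                                 summarizeLevel(c(4, 4))))
  expect_equal(poolMean(eq), 2)
  uneq <- weightedMeanByCount(list(LevelSummary(0, 1, 1), LevelSummary(4, 1, 3)))
  expect_equal(poolMean(uneq), 3)
  set.seed(72)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    ns <- sample(2:20, k, replace = TRUE)
    ms <- runif(k, 0, 50)
    sums <- lapply(seq_len(k), function(i) LevelSummary(ms[i], runif(1), ns[i]))
    flat <- rep(ms, ns)                      # expansion oracle for the mean
    got <- weightedMeanByCount(sums)
    expect_equal(poolMean(got), mean(flat), tolerance = 1e-12)
    expect_equal(got@n, sum(ns))
  }
})

test_that("inverse-variance pooling matches the closed form", {
  single <- inverseVariancePool(list(LevelSummary(3.5, 0.7, 5)))
  expect_equal(poolMean(single), 3.5)
  expect_equal(poolVariance(single), 0.7)
  sym <- inverseVariancePool(list(LevelSummary(2, 0.5, 5),
                                  LevelSummary(8, 0.5, 5)))
  expect_equal(poolMean(sym), 5)
  expect_equal(poolVariance(sym), 0.25)
  set.seed(73)
  for (rep in 1:10) {
    m <- runif(3, -5, 5); v <- runif(3, 0.1, 2)
    got <- inverseVariancePool(lapply(1:3, function(i)
      LevelSummary(m[i], v[i], 5L)))
    expect_equal(poolMean(got), sum(m / v) / sum(1 / v), tolerance = 1e-12)
    expect_equal(poolVariance(got), 1 / sum(1 / v), tolerance = 1e-12)
    expect_equal(sum(poolWeights(got)), 1, tolerance = 1e-12)
    expect_lte(poolVariance(got), min(v))
  }
})

test_that("degenerate variances fall back as documented", {
  mixed <- inverseVariancePool(list(LevelSummary(1, 0, 1),
                                    LevelSummary(3, 0.5, 4),
                                    LevelSummary(5, 2, 4)))
  ## the zero-variance member is given the smallest positive variance (0.5)
  w <- poolWeights(mixed)
  expect_equal(w[1], w[2], tolerance = 1e-12)
  allzero <- inverseVariancePool(list(LevelSummary(2, 0, 1),
                                      LevelSummary(4, 0, 3)))
  expect_equal(poolMean(allzero), 3.5)    # count weighting: (2*1 + 4*3)/4
  expect_equal(poolVariance(allzero), 0)
})

test_that("the hierarchical chain reduces to identity on a single picture", {
  d <- data.frame(experiment = 1, replicate = 1, picture_id = "p",
                  value = c(4, 6, 8))
  pe <- hierarchicalNeuriteMean(d)
  expect_equal(poolMean(pe), 6)
  cst <- data.frame(experiment = rep(1:2, each = 4), replicate = 1,
                    picture_id = rep(c("a", "b", "c", "d"), each = 2),
                    value = 7)
  expect_equal(poolMean(hierarchicalNeuriteMean(cst)), 7)
})

test_that("the hierarchical estimate ignores input ordering", {
  hh <- generateMeasurementHierarchy(hierarchySpec(), seed = 74)
  pe1 <- hierarchicalNeuriteMean(hh$data)
  set.seed(75)
  shuffled <- hh$data[sample(nrow(hh$data)), ]
  pe2 <- hierarchicalNeuriteMean(shuffled)
  expect_equal(poolMean(pe2), poolMean(pe1), tolerance = 1e-12)
  expect_equal(poolVariance(pe2), poolVariance(pe1), tolerance = 1e-12)
})

test_that("estimator bias shrinks as experiments accumulate", {
  bias <- vapply(c(10L, 50L, 200L), function(ne) {
    hh <- generateMeasurementHierarchy(hierarchySpec(nExperiments = ne),
                                       seed = 76)
    abs(poolMean(hierarchicalNeuriteMean(hh$data)) - 60)
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 1e-9)
  ## and the final estimate sits within 3 standard errors, where the SE of
  ## the Monte-Carlo recovery comes from the between-experiment spread (the
  ## pool's internal variance deliberately tracks only within-experiment
  ## scatter, mirroring the inverse-variance weighting chain)
  hh <- generateMeasurementHierarchy(hierarchySpec(nExperiments = 200L),
                                     seed = 77)
  pe <- hierarchicalNeuriteMean(hh$data)
  expMeans <- tapply(hh$data$value, hh$data$experiment, mean)
  se <- stats::sd(expMeans) / sqrt(length(expMeans))
  expect_lt(abs(poolMean(pe) - 60), 3 * se)
})

test_that("assay normalization divides by protein then control", {
  expect_equal(normalizeAssay(10, 2, 5), 1)
  expect_equal(normalizeAssay(10, NULL, 10), 1)
  expect_error(normalizeAssay(10, 0, 5), "protein")
  expect_error(normalizeAssay(10, 2, 0), "control")
})
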