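test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(81)
  for (rep in 1:5) {
    a <- rnorm(sample(4:12, 1), 0, 1)
    b <- rnorm(sample(4:12, 1), 0.8, 1)
    res <- oneWayAnova(list(a = a, b = b))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res@fStatistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res@pValue, tt$p.value, tolerance = 1e-10)
    expect_equal(res@dfWithin, length(a) + length(b) - 2L)
  }
})

test_that("equal group means give F = 0 and p = 1", {
  g <- list(a = c(1, 2, 3), b = c(0, 2, 4), c = c(-1, 2, 5))  # all means 2
  res <- oneWayAnova(g)
  expect_equal(res@fStatistic, 0, tolerance = 1e-12)
  expect_equal(res@pValue, 1, tolerance = 1e-9)
})

test_that("p decreases monotonically in F at fixed dfs", {
  fs <- c(0.5, 1, 2, 4, 8)
  ps <- stats::pf(fs, 2, 12, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  ## and the ANOVA preconditions are enforced
  expect_error(oneWayAnova(list(a = 1:3)), "two groups")
  expect_error(oneWayAnova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  expect_error(oneWayAnova(list(a = c(1), b = c(1, 2))), "at least two values")
})

test_that("Tukey flags no pairs on identical groups", {
  set.seed(82)
  base <- rnorm(8)
  g <- list(a = base, b = base + 1e-12, c = base - 1e-12)
  res <- tukeyHsd(g)
  expect_false(any(res$significant))
  expect_equal(nrow(res), 3L)
})

test_that("a strongly shifted group is detected in nearly all replicates", {
  hits <- 0L
  for (rep in 1:50) {
    set.seed(8200 + rep)
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 10)
    res <- tukeyHsd(g)
    withC <- res$significant[res$group_a == "c" | res$group_b == "c"]
    if (all(withC)) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.99)
})

test_that("Tukey-Kramer agrees with stats::TukeyHSD on unbalanced groups", {
  set.seed(83)
  g <- list(a = rnorm(6), b = rnorm(9, 1), c = rnorm(4, 2))
  res <- tukeyHsd(g)
  df <- data.frame(y = unlist(g), grp = factor(rep(names(g), lengths(g))))
  ref <- stats::TukeyHSD(stats::aov(y ~ grp, df))$grp
  for (i in seq_len(nrow(res))) {
    key <- paste0(res$group_b[i], "-", res$group_a[i])
    expect_equal(res$mean_difference[i], ref[key, "diff"], tolerance = 1e-9)
    expect_equal(res$p_value[i], ref[key, "p adj"], tolerance = 1e-9)
  }
})

test_that("the significant set grows monotonically with effect size", {
  set.seed(84)
  base <- list(a = rnorm(10), b = rnorm(10))
  nsig <- vapply(c(0, 2, 6), function(shift) {
    g <- c(base, list(c = rnorm(10) + shift))
    sum(tukeyHsd(g)$significant)
  }, numeric(1))
  expect_true(all(diff(nsig) >= 0))
  expect_gt(nsig[3], 0)
})

test_that("determination coefficient follows the normal equations", {
  expect_equal(determinationCoefficient(1:5, 2 * (1:5) + 1)@rSquared, 1)
  set.seed(85)
  for (rep in 1:5) {
    x <- runif(30); y <- 2 * x + rnorm(30, 0, 0.3)
    got <- determinationCoefficient(x, y)
    ## normal-equations oracle
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    alpha <- mean(y) - beta * mean(x)
    r2 <- 1 - sum((y - alpha - beta * x)^2) / sum((y - mean(y))^2)
    expect_equal(got@rSquared, r2, tolerance = 1e-10)
  }
  expect_error(determinationCoefficient(1:5, rep(2, 5)), "constant")
  expect_error(determinationCoefficient(1:2, 1:2), "3 pairs")
})

test_that("independent noise yields a near-zero determination coefficient", {
  set.seed(86)
  x <- rnorm(1000)
  y <- sample(x)   # independent permutation
  expect_lt(determinationCoefficient(x, y)@rSquared, 0.05)
})
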