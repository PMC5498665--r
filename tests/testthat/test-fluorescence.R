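test_that("threshold selection honours fixed and Otsu policies", {
  img <- Micrograph(matrix(c(rep(10, 90), rep(200, 10)), 10, 10),
                    bitDepth = 8L)
  expect_equal(selectThreshold(img, thresholdPolicy("fixed", 500)), 500)
  t <- selectThreshold(img, thresholdPolicy("otsu"))
  expect_gt(t, 10); expect_lt(t, 200)
  flat <- Micrograph(matrix(7, 8, 8), bitDepth = 8L)
  expect_error(selectThreshold(flat, thresholdPolicy("otsu")), "single")
  expect_error(thresholdPolicy("fixed"), "fixed_value")
})

test_that("Otsu equals an exhaustive between-class-variance scan", {
  set.seed(61)
  for (rep in 1:5) {
    v <- round(c(rnorm(300, 60, 12), rnorm(150, 180, 15)))
    v <- pmin(pmax(v, 0), 255)
    img <- Micrograph(matrix(v, 30, 15), bitDepth = 8L)
    got <- selectThreshold(img, thresholdPolicy("otsu"))
    ## brute force over every candidate cut; the implementation reports the
    ## midpoint between the optimal cut level and the next level
    lev <- sort(unique(v))
    best <- -Inf; bestI <- NA
    for (i in seq_len(length(lev) - 1L)) {
      lo <- v[v <= lev[i]]; hi <- v[v > lev[i]]
      bc <- length(lo) * length(hi) / length(v)^2 *
            (mean(lo) - mean(hi))^2
      if (bc > best) { best <- bc; bestI <- i }
    }
    expect_equal(got, (lev[bestI] + lev[bestI + 1]) / 2)
  }
})

test_that("suprathreshold sum is strict and matches a pixel loop", {
  img <- Micrograph(matrix(c(1, 7, 5, 3), 2, 2), bitDepth = 8L)
  expect_equal(suprathresholdSum(img, 4), 12)
  expect_equal(suprathresholdSum(img, 7), 0)   # strict: 7 does not count
  expect_equal(suprathresholdSum(img, 255), 0)
  set.seed(62)
  for (rep in 1:50) {
    px <- matrix(sample(0:4095, 64 * 64, replace = TRUE), 64, 64)
    img <- Micrograph(px, bitDepth = 16L)
    thr <- runif(1, 0, 4095)
    oracle <- 0
    for (v in as.vector(px)) if (v > thr) oracle <- oracle + v
    expect_equal(suprathresholdSum(img, thr), oracle)
  }
})

test_that("suprathreshold sum never increases along a threshold sweep", {
  set.seed(63)
  img <- Micrograph(matrix(sample(0:65535, 128 * 128, replace = TRUE),
                           128, 128), bitDepth = 16L)
  sums <- vapply(seq(0, 65535, length.out = 60), function(t)
    suprathresholdSum(img, t), numeric(1))
  expect_true(all(diff(sums) <= 0))
})

test_that("RFI divides marker by nucleus and fails without a normalizer", {
  mk <- Micrograph(matrix(0, 8, 8), bitDepth = 8L)
  nuc <- Micrograph(matrix(c(rep(0, 60), rep(200, 4)), 8, 8), bitDepth = 8L)
  pol <- thresholdPolicy("fixed", 100)
  r <- rfi(mk, nuc, pol)
  expect_equal(r@rfi, 0)
  expect_equal(r@nucleusSum, 800)
  expect_error(rfi(mk, mk, pol), "normalizer")
  expect_error(rfi(mk, Micrograph(matrix(0, 4, 4), bitDepth = 8L), pol),
               "shape")
})

test_that("noise-free generated pairs reproduce the true RFI exactly", {
  fp <- generateFluorescencePair(fluorPairSpec(noiseSd = 0), seed = 8)
  pol <- thresholdPolicy("fixed", fp$truth$threshold)
  r <- rfi(fp$marker, fp$nucleus, pol)
  expect_identical(r@markerSum, fp$truth$marker_sum)
  expect_identical(r@nucleusSum, fp$truth$nucleus_sum)
  expect_equal(r@rfi, fp$truth$rfi)
})

test_that("RFI error shrinks as noise decreases", {
  ## mean absolute error over 5 seeds at three decreasing noise levels
  errs <- vapply(c(4000, 800, 100), function(ns) {
    mean(vapply(1:5, function(s) {
      fp <- generateFluorescencePair(fluorPairSpec(noiseSd = ns), seed = s)
      r <- rfi(fp$marker, fp$nucleus,
               thresholdPolicy("fixed", fp$truth$threshold))
      abs(r@rfi - fp$truth$rfi)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("fixed-threshold RFI is scale invariant when thresholds scale too", {
  fp <- generateFluorescencePair(fluorPairSpec(noiseSd = 0,
                                               markerAmplitude = 20000,
                                               nucleusAmplitude = 16000),
                                 seed = 10)
  pol1 <- thresholdPolicy("fixed", fp$truth$threshold)
  r1 <- rfi(fp$marker, fp$nucleus, pol1)
  half <- function(m) Micrograph(floor(pixels(m) / 2), bitDepth = 16L)
  pol2 <- thresholdPolicy("fixed", fp$truth$threshold / 2)
  r2 <- rfi(half(fp$marker), half(fp$nucleus), pol2)
  expect_equal(r2@rfi, r1@rfi, tolerance = 0.01)
})
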