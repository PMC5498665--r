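test_that("IDV follows sum minus mean-background times area", {
  ## uniform image: any same-size ROI pair gives 0
  img <- Micrograph(matrix(500, 40, 40), bitDepth = 16L)
  q <- integratedDensity(img, ROI(5, 5, 4, 4), ROI(20, 20, 4, 4),
                         invert = FALSE)
  expect_equal(idv(q), 0)
  ## hand-arithmetic case: 2x2 band of 10 over background mean 2
  px <- matrix(2, 20, 20); px[3:4, 3:4] <- 10
  img2 <- Micrograph(px, bitDepth = 8L)
  q2 <- integratedDensity(img2, ROI(3, 3, 2, 2), ROI(10, 10, 2, 2),
                          invert = FALSE)
  expect_equal(idv(q2), 40 - 8)
  expect_equal(q2@backgroundMeanPerPx, 2)
})

test_that("ROI bounds, dimension and overlap violations fail", {
  img <- Micrograph(matrix(0, 30, 30))
  expect_error(integratedDensity(img, ROI(25, 25, 10, 10), ROI(1, 1, 10, 10)),
               "bounds")
  expect_error(integratedDensity(img, ROI(1, 1, 4, 4), ROI(10, 10, 5, 4)),
               "dimensions")
  expect_error(integratedDensity(img, ROI(1, 1, 6, 6), ROI(4, 4, 6, 6)),
               "overlap")
})

test_that("IDV is linear in gain and invariant to constant offsets", {
  set.seed(51)
  base <- matrix(runif(900, 100, 200), 30, 30)
  roiB <- ROI(4, 4, 6, 6); roiG <- ROI(20, 20, 6, 6)
  i1 <- idv(integratedDensity(Micrograph(round(base)), roiB, roiG,
                              invert = FALSE))
  i2 <- idv(integratedDensity(Micrograph(round(base) * 2), roiB, roiG,
                              invert = FALSE))
  expect_equal(i2, i1 * 2, tolerance = 1e-12)
  i3 <- idv(integratedDensity(Micrograph(round(base) + 300), roiB, roiG,
                              invert = FALSE))
  expect_equal(i3, i1, tolerance = 1e-9)
})

test_that("uniform-ROI enforcement names the offender", {
  a <- ROI(1, 1, 20, 60); b <- ROI(40, 7, 20, 60); c <- ROI(1, 80, 20, 61)
  expect_identical(enforceUniformRoi(list(a)), list(a))
  expect_identical(enforceUniformRoi(list(a, b)), list(a, b))
  expect_error(enforceUniformRoi(list(a, c)), "index 2")
  expect_error(enforceUniformRoi(list()), "empty")
})

test_that("band normalization and fold change follow their definitions", {
  mk <- function(v) new("BandQuant", idv = v, roi = ROI(1, 1, 2, 2),
                        backgroundMeanPerPx = 0)
  expect_equal(normalizeBand(mk(32), mk(32)), 1)
  expect_equal(normalizeBand(mk(0), mk(50)), 0)
  expect_error(normalizeBand(mk(5), mk(0)), "not positive")
  expect_warning(r <- normalizeBand(mk(-5), mk(50)), "negative")
  expect_equal(r, -0.1)
  expect_equal(foldChange(c(ctl = 2, a = 4), "ctl"), c(ctl = 1, a = 2))
  set.seed(52)
  v <- stats::setNames(runif(5, 0.5, 4), letters[1:5])
  expect_equal(foldChange(v, "c"), v / v[["c"]])
  expect_error(foldChange(c(a = 1), "zz"), "missing")
})

test_that("noise-free generated lanes recover planted ratios within 2%", {
  amps <- six_lane_amps()
  b <- generateBlotImage(blotSpec(amps, noiseSd = 0), seed = 6)
  rois <- defaultBlotRois(b$truth)
  for (j in seq_along(rois)) {
    t <- integratedDensity(b$image, rois[[j]]$target, rois[[j]]$target_bg)
    l <- integratedDensity(b$image, rois[[j]]$loading, rois[[j]]$loading_bg)
    r <- normalizeBand(t, l)
    expect_lt(abs(r - b$truth$lanes[[j]]$ratio) / b$truth$lanes[[j]]$ratio,
              0.02)
  }
})

test_that("lane order permutation permutes outputs identically", {
  amps <- six_lane_amps()
  perm <- c(3, 1, 6, 2, 5, 4)
  b1 <- generateBlotImage(blotSpec(amps, noiseSd = 0), seed = 7)
  b2 <- generateBlotImage(blotSpec(amps[perm, ], noiseSd = 0), seed = 7)
  r1 <- vapply(b1$truth$lanes, function(l) l$ratio, numeric(1))
  r2 <- vapply(b2$truth$lanes, function(l) l$ratio, numeric(1))
  expect_equal(r2, r1[perm], tolerance = 1e-9)
})
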