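test_that("polyline length follows chained Euclidean distances", {
  expect_equal(polylineLengthPx(Polyline(rbind(c(0, 0)))), 0)
  expect_equal(polylineLengthPx(Polyline(rbind(c(0, 0), c(3, 4)))), 5)
  set.seed(41)
  for (rep in 1:10) {
    v <- matrix(runif(20, 0, 200), 10, 2)
    oracle <- 0
    for (i in 1:9) oracle <- oracle +
      sqrt((v[i + 1, 1] - v[i, 1])^2 + (v[i + 1, 2] - v[i, 2])^2)
    expect_equal(polylineLengthPx(Polyline(v)), oracle, tolerance = 1e-12)
  }
})

test_that("polyline length is invariant under translation and rotation", {
  set.seed(42)
  v <- matrix(runif(16, 0, 100), 8, 2)
  base <- polylineLengthPx(Polyline(v))
  for (rep in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- runif(2, -50, 50)
    v2 <- sweep(v %*% R, 2, -shift)
    expect_equal(polylineLengthPx(Polyline(v2)), base, tolerance = 1e-9)
  }
})

test_that("longest path picks the longest branch and matches enumeration", {
  single <- NeuriteTree(c(0, 0), rbind(c(0, 0), c(12.5, 0)),
                        data.frame(parent = 1, child = 2, weight = 12.5))
  expect_equal(longestPathLengthPx(single), 12.5)
  y <- NeuriteTree(c(0, 0), rbind(c(0, 0), c(20, 0), c(50, 0), c(40, 30)),
                   data.frame(parent = c(1, 2, 2), child = c(2, 3, 4),
                              weight = c(20, 30, 50)))
  expect_equal(longestPathLengthPx(y), 70)
  set.seed(43)
  for (rep in 1:20) {
    tr <- random_tree(12L)
    paths <- enumerate_path_lengths(tr)
    expect_equal(longestPathLengthPx(tr), max(paths), tolerance = 1e-12)
    ## dominates every individual root-to-leaf path
    expect_true(all(longestPathLengthPx(tr) >= paths - 1e-12))
  }
})

test_that("tree validity rejects malformed structures", {
  expect_error(NeuriteTree(c(0, 0), rbind(c(0, 0), c(1, 1)),
    data.frame(parent = c(1, 2), child = c(2, 1), weight = c(1, 1))),
    "n - 1 edges")
  expect_error(NeuriteTree(c(0, 0), rbind(c(0, 0), c(1, 1), c(2, 2)),
    data.frame(parent = c(1, 3), child = c(2, 2), weight = c(1, 1))),
    "exactly one parent")
})

test_that("calibration converts pixel lengths through the scale bar", {
  expect_equal(calibrateLength(0, 0.5), 0)
  expect_equal(calibrateLength(200, 0.5), 100)
  expect_equal(scaleFromBar(100, 250), 0.4)
  expect_equal(calibrateLength(10, scaleFromBar(100, 250)), 4)
  expect_error(calibrateLength(10, NA), "calibration")
})

test_that("measurePicture applies the right rule per input type", {
  p <- Polyline(rbind(c(0, 0), c(3, 4)))
  res <- measurePicture(list(p), 1, "p1")
  expect_equal(res$lengths_um, 5)
  expect_equal(res$n, 1L)
  y <- NeuriteTree(c(0, 0), rbind(c(0, 0), c(20, 0), c(50, 0), c(40, 30)),
                   data.frame(parent = c(1, 2, 2), child = c(2, 3, 4),
                              weight = c(20, 30, 50)))
  mixed <- measurePicture(list(p, y), 0.5, "p2")
  expect_equal(mixed$n, 2L)
  expect_equal(mixed$lengths_um, c(2.5, 35))
  expect_error(measurePicture(list(), 1, "p3"), "no measurements")
})

test_that("annotation-mode measurement of truth polylines is exact", {
  sc <- generateNeuronScene(small_scene_spec(), seed = 13)
  cal <- sc$truth$um_per_px
  polys <- lapply(sc$truth$neurites, function(nt)
    Polyline(nt$paths[[which.max(vapply(nt$paths,
      function(v) polylineLengthPx(Polyline(v)), numeric(1)))]]))
  res <- measurePicture(polys, cal, "scene")
  truth <- vapply(sc$truth$neurites, function(nt) nt$length_um, numeric(1))
  expect_equal(res$lengths_um, truth, tolerance = 1e-9)
})

test_that("enhancement returns a same-shape map, blank on constant input", {
  flat <- Micrograph(matrix(1200, 64, 64))
  em <- enhanceNeurites(flat)
  expect_identical(dim(em), c(64L, 64L))
  expect_false(any(em))
})

test_that("every drawn line pixel lies within 2 px of an enhanced edge", {
  ## single bright straight stroke, no noise
  h <- 96; w <- 96
  cov <- neurimetry:::segment_coverage(h, w, c(20, 15), c(70, 80), 2.5)
  img <- Micrograph(neurimetry:::quantize_raster(6000 + 34000 * cov, 16L))
  em <- enhanceNeurites(img)
  line_px <- which(cov > 0.5, arr.ind = TRUE)
  edge_px <- which(em, arr.ind = TRUE)
  expect_gt(nrow(edge_px), 0)
  for (i in seq_len(nrow(line_px))) {
    d <- min(sqrt((edge_px[, 1] - line_px[i, 1])^2 +
                  (edge_px[, 2] - line_px[i, 2])^2))
    expect_lte(d, 2)
  }
})

test_that("edge maps overlap the drawn neurite mask on generated scenes", {
  sc <- generateNeuronScene(study_scene_spec(), seed = 17)
  em <- enhanceNeurites(sc$image)
  ## the drawn strokes are thin; allow 2 px of slack by dilating the mask
  ## before comparing against the (already band-like) edge map
  dil <- EBImage::dilate(sc$neuriteMask * 1, EBImage::makeBrush(5, "disc")) > 0
  inter <- sum(em & dil)
  uni <- sum(em | dil)
  expect_gte(inter / uni, 0.5)
})

test_that("binarization is idempotent and overlays are lossless off-edge", {
  sc <- generateNeuronScene(small_scene_spec(), seed = 19)
  em <- enhanceNeurites(sc$image)
  expect_identical(em, em & em)
  ov <- overlayEdges(sc$image, em)
  g <- pixels(sc$image) / 65535
  off <- !em
  expect_equal(ov[, , 1][off], g[off])
  expect_equal(ov[, , 3][off], g[off])
  expect_true(all(ov[, , 3][em] == 1) && all(ov[, , 1][em] == 0))
  ## empty and full maps
  none <- matrix(FALSE, nrow(g), ncol(g))
  expect_equal(overlayEdges(sc$image, none)[, , 2], g)
  allb <- overlayEdges(sc$image, !none)
  expect_true(all(allb[, , 3] == 1))
  expect_error(overlayEdges(sc$image, none[1:10, 1:10]), "shape")
})
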