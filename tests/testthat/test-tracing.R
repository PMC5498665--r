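test_that("blank edge maps and missing somata are handled explicitly", {
  soma <- matrix(FALSE, 32, 32); soma[14:18, 14:18] <- TRUE
  expect_identical(traceNeurites(matrix(FALSE, 32, 32), soma), list())
  expect_error(traceNeurites(matrix(TRUE, 32, 32), matrix(FALSE, 32, 32)),
               "soma")
})

test_that("an unbranched synthetic neurite is recovered within 5%", {
  sc <- generateNeuronScene(
    neuronSceneSpec(imageHeightPx = 192L, imageWidthPx = 192L, nCells = 1L,
                    neuritesPerCell = 1L, branchProbability = 0,
                    neuriteLengthPxRange = c(45, 45), noiseSd = 0), seed = 21)
  edges <- enhanceNeurites(sc$image)
  trees <- traceNeurites(edges, sc$somaMask, image = sc$image)
  expect_length(trees, 1L)
  got <- longestPathLengthPx(trees[[1]])
  expect_lt(abs(got - sc$truth$neurites[[1]]$length_px) /
            sc$truth$neurites[[1]]$length_px, 0.05)
})

test_that("a Y-branched neurite recovers the longest path (stem 20, arms 30/50)", {
  h <- 192L; w <- 192L
  ctr <- c(96, 40); somaR <- 8
  stem_end <- ctr + c(0, somaR + 20)
  armA_end <- stem_end + 50 * c(sin(0.45), cos(0.45))
  armB_end <- stem_end + 30 * c(-sin(0.45), cos(0.45))
  segs <- list(list(ctr + c(0, somaR), stem_end),
               list(stem_end, armA_end), list(stem_end, armB_end))
  cov <- matrix(0, h, w)
  for (s in segs)
    cov <- pmax(cov, neurimetry:::segment_coverage(h, w, s[[1]], s[[2]], 2.5))
  soma_cov <- neurimetry:::disk_coverage(h, w, ctr, somaR)
  img <- Micrograph(neurimetry:::quantize_raster(
    6000 + 34000 * pmax(cov, soma_cov), 16L))
  edges <- enhanceNeurites(img)
  trees <- traceNeurites(edges, soma_cov > 0.5, image = img)
  expect_length(trees, 1L)
  got <- longestPathLengthPx(trees[[1]])
  expect_lt(abs(got - 70) / 70, 0.05)
  ## the tree really has two leaves and obeys the enumeration oracle
  paths <- enumerate_path_lengths(trees[[1]])
  expect_gte(length(paths), 2L)
  expect_equal(got, max(paths), tolerance = 1e-9)
})

test_that("traced trees satisfy the NeuriteTree invariants", {
  sc <- generateNeuronScene(study_scene_spec(), seed = 23)
  edges <- enhanceNeurites(sc$image)
  trees <- traceNeurites(edges, sc$somaMask, image = sc$image)
  expect_length(trees, 10L)
  for (t in trees) expect_true(validObject(t))
  ## every tree is anchored near some true anchor
  m <- matchTracedToTruth(trees, sc$truth)
  expect_true(all(m$anchor_dist_px < 4))
})

test_that("sub-minimum skeleton stubs are discarded", {
  sc <- generateNeuronScene(
    neuronSceneSpec(imageHeightPx = 192L, imageWidthPx = 192L, nCells = 1L,
                    neuritesPerCell = 1L, branchProbability = 0,
                    neuriteLengthPxRange = c(40, 40), noiseSd = 0), seed = 25)
  edges <- enhanceNeurites(sc$image)
  trees <- traceNeurites(edges, sc$somaMask, min_length_px = 1000,
                         image = sc$image)
  expect_length(trees, 0L)
})
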