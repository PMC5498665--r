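test_that("scene generation is a pure function of (spec, seed)", {
  spec <- small_scene_spec(noiseSd = 300)
  a <- generateNeuronScene(spec, seed = 7)
  b <- generateNeuronScene(spec, seed = 7)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth, b$truth)
  c <- generateNeuronScene(spec, seed = 8)
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("an empty scene is background plus noise with empty truth", {
  spec <- neuronSceneSpec(nCells = 0L, noiseSd = 0,
                          backgroundIntensity = 6000)
  sc <- generateNeuronScene(spec, seed = 1)
  expect_true(all(pixels(sc$image) == 6000))
  expect_length(sc$truth$neurites, 0)
  expect_false(any(sc$somaMask))
})

test_that("stored truth lengths equal an independent segment-sum oracle", {
  sc <- generateNeuronScene(study_scene_spec(), seed = 11)
  expect_length(sc$truth$neurites, 10L)
  for (nt in sc$truth$neurites) {
    oracle <- max(vapply(nt$paths, function(v) {
      if (nrow(v) < 2) return(0)
      s <- 0
      for (i in seq_len(nrow(v) - 1L))
        s <- s + sqrt(sum((v[i + 1L, ] - v[i, ])^2))
      s
    }, numeric(1)))
    expect_equal(nt$length_px, oracle, tolerance = 1e-12)
    expect_equal(nt$length_um, oracle * sc$truth$um_per_px, tolerance = 1e-12)
    ## lengths respect the requested range
    expect_gte(nt$length_px, 30 - 1e-9)
    expect_lte(nt$length_px, 55 + 1e-9)
  }
})

test_that("infeasible geometry fails naming a spec field", {
  spec <- neuronSceneSpec(imageHeightPx = 64L, imageWidthPx = 64L,
                          nCells = 10L)
  expect_error(generateNeuronScene(spec, seed = 1), "n_cells")
})

test_that("spec invariants are enforced at construction", {
  expect_error(neuronSceneSpec(neuriteLengthPxRange = c(50, 30)), "min")
  expect_error(neuronSceneSpec(foregroundIntensity = 10,
                               backgroundIntensity = 20), "exceed")
  expect_error(neuronSceneSpec(branchProbability = 1.5), "branchProbability")
})

test_that("the drawn raster honours intensity bounds and masks", {
  sc <- generateNeuronScene(small_scene_spec(), seed = 3)
  px <- pixels(sc$image)
  expect_true(all(px >= 0 & px <= 65535))
  ## somata are bright in the noise-free render; mask pixels have coverage
  ## > 0.5, so intensity >= background + 0.5 * (foreground - background)
  expect_gte(min(px[sc$somaMask]), 23000 - 1)
  expect_true(any(sc$neuriteMask))
})
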