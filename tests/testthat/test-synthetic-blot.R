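test_that("zero-amplitude lanes give a pure background ramp and zero IDVs", {
  spec <- blotSpec(rbind(c(0, 0), c(0, 0)), noiseSd = 0,
                   backgroundLevel = 50000, backgroundGradient = 2)
  b <- generateBlotImage(spec, seed = 1)
  px <- pixels(b$image)
  expect_equal(px[1, 1], 50000)
  expect_equal(px[1, 2], 50002)
  expect_true(all(diff(t(px)[, 1]) == 2))   # constant ramp along columns
  expect_true(all(vapply(b$truth$lanes, function(l)
    l$target_idv == 0 && l$loading_idv == 0, logical(1))))
})

test_that("true integrated signal equals direct summation of the analytic bump", {
  A <- 8000; sig <- 12
  spec <- blotSpec(rbind(c(A, 0)), bandSigmaPx = sig, noiseSd = 0)
  b <- generateBlotImage(spec, seed = 1)
  ln <- b$truth$lanes[[1]]
  h <- b$truth$image_shape[1]; w <- b$truth$image_shape[2]
  oracle <- 0
  for (r in seq_len(h)) for (c0 in seq_len(w))
    oracle <- oracle + A * exp(-((r - ln$target_row)^2 +
                                 (c0 - ln$centre_col)^2) / (2 * sig^2))
  expect_equal(ln$target_idv, oracle, tolerance = 1e-9)
})

test_that("blot generation is deterministic and validates its spec", {
  spec <- blotSpec(six_lane_amps(), noiseSd = 100)
  a <- generateBlotImage(spec, seed = 4)
  b <- generateBlotImage(spec, seed = 4)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_error(blotSpec(six_lane_amps(), bandSigmaPx = 30, lanePitchPx = 100),
               "overlap")
  expect_error(generateBlotImage(blotSpec(rbind(c(60000, 100)),
                                          backgroundLevel = 52000), seed = 1),
               "amplitude exceeds")
})

test_that("planted target/loading ratios are recorded per lane", {
  amps <- six_lane_amps()
  b <- generateBlotImage(blotSpec(amps), seed = 2)
  ## discrete raster truncation perturbs the integrals by ~1e-5 relative
  for (j in seq_len(nrow(amps)))
    expect_equal(b$truth$lanes[[j]]$ratio, amps[j, 1] / amps[j, 2],
                 tolerance = 1e-4)
})
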