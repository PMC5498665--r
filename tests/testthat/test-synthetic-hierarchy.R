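test_that("zero variance components collapse to the grand mean", {
  spec <- hierarchySpec(sdBetweenExperiments = 0, sdBetweenPictures = 0,
                        sdWithinPicture = 0, grandMean = 42)
  hh <- generateMeasurementHierarchy(spec, seed = 1)
  expect_true(all(hh$data$value == 42))
})

test_that("per-picture counts stay within the requested 15-30 range", {
  hh <- generateMeasurementHierarchy(hierarchySpec(), seed = 2)
  counts <- table(hh$data$picture_id)
  expect_true(all(counts >= 15 & counts <= 30))
  ## design shape: experiments x replicates x pictures
  expect_equal(length(unique(hh$data$picture_id)), 3L * 2L * 5L)
})

test_that("hierarchy generation is deterministic and truth matches draws", {
  a <- generateMeasurementHierarchy(hierarchySpec(), seed = 3)
  b <- generateMeasurementHierarchy(hierarchySpec(), seed = 3)
  expect_identical(a$data, b$data)
  expect_length(a$truth$experiment_offsets, 3L)
})

test_that("assay tables plant exact fold changes at zero noise", {
  at <- generateAssayTable(c("ctrl", "low", "high"), c(1, 1.5, 3), 4L,
                           noise_cv = 0, seed = 1)
  na <- normalizeAssayTable(at$data, "ctrl")
  expect_equal(as.numeric(na$fold_changes), c(1, 1.5, 3),
               tolerance = 1e-12)
  a2 <- generateAssayTable(c("ctrl", "low", "high"), c(1, 1.5, 3), 4L,
                           noise_cv = 0.1, seed = 1)
  a3 <- generateAssayTable(c("ctrl", "low", "high"), c(1, 1.5, 3), 4L,
                           noise_cv = 0.1, seed = 1)
  expect_identical(a2$data, a3$data)
})

test_that("assay generation validates its control flag", {
  expect_error(generateAssayTable(c("a", "b"), c(1, 2), 3L, 0.1,
                                  control = "zz"), "control")
  expect_error(generateAssayTable(c("a", "b"), c(2, 1), 3L, 0.1,
                                  control = "a"), "fold change must be 1")
})

test_that("null assay tables reject at close to the nominal ANOVA rate", {
  reps <- 1000L
  rejections <- 0L
  for (r in seq_len(reps)) {
    at <- generateAssayTable(c("c", "t1", "t2"), c(1, 1, 1), 6L,
                             noise_cv = 0.15, seed = 20000 + r)
    na <- normalizeAssayTable(at$data, "c")
    groups <- split(na$per_row$normalized, na$per_row$condition)
    res <- oneWayAnova(groups)
    if (res@pValue < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
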