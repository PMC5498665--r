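#' Generate a synthetic two-channel immunofluorescence pair
#'
#' The nucleus channel contains \code{nNuclei} anti-aliased stained disks;
#' the marker channel contains disks at the same positions for the positive
#' fraction of objects. Ground truth records the exact suprathreshold
#' cumulative sum of each noise-free channel at \code{thresholdTruth}
#' (computed by direct pixel enumeration of the quantized noise-free rasters)
#' and the true marker/nucleus RFI ratio.
#'
#' @param spec a \linkS4class{FluorPairSpec}.
#' @param seed integer seed.
#' @return List with \code{marker} and \code{nucleus}
#'   (\linkS4class{Micrograph}) and \code{truth} (list: \code{kind =
#'   "fluorescence"}, \code{threshold}, \code{marker_sum},
#'   \code{nucleus_sum}, \code{rfi}, object centres and positivity flags).
#' @examples
#' fp <- generateFluorescencePair(fluorPairSpec(nNuclei = 4L), seed = 2)
#' fp$truth$rfi
#' @export
generateFluorescencePair <- function(spec, seed = 0L) {
  stopifnot(is(spec, "FluorPairSpec"))
  validObject(spec)
  with_seed(seed, .generate_fluor_pair(spec))
}

.generate_fluor_pair <- function(spec) {
  h <- spec@imageShape[1]; w <- spec@imageShape[2]
  r <- spec@nucleusRadiusPx
  n <- spec@nNuclei

  centres <- matrix(numeric(0), 0, 2)
  if (n > 0L) {
    lo <- r + 2
    if (h - r - 2 < lo || w - r - 2 < lo)
      stop("image too small for the requested nucleus radius")
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:400) {
        cand <- c(runif(1, lo, h - r - 2), runif(1, lo, w - r - 2))
        if (nrow(centres) == 0L ||
            all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >= 2 * r + 2)) {
          centres <- rbind(centres, cand); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("cannot place ", n, " non-overlapping nuclei; reduce n_nuclei ",
             "or nucleus_radius_px, or enlarge image_shape")
    }
  }

  nPos <- round(spec@markerFractionPositive * n)
  positive <- if (n > 0L) sort(sample.int(n, nPos)) else integer(0)

  nucClean <- matrix(0, h, w)
  mrkClean <- matrix(0, h, w)
  for (i in seq_len(n)) {
    cov <- disk_coverage(h, w, centres[i, ], r)
    nucClean <- pmax(nucClean, cov * spec@nucleusAmplitude)
    if (i %in% positive)
      mrkClean <- pmax(mrkClean, cov * spec@markerAmplitude)
  }
  nucClean <- quantize_raster(nucClean, 16L)
  mrkClean <- quantize_raster(mrkClean, 16L)

  thr <- spec@thresholdTruth
  mSum <- sum(mrkClean[mrkClean > thr])
  nSum <- sum(nucClean[nucClean > thr])

  addNoise <- function(clean) {
    px <- clean
    if (spec@noiseSd > 0) px <- px + rnorm(h * w, 0, spec@noiseSd)
    quantize_raster(px, 16L)
  }
  marker  <- Micrograph(addNoise(mrkClean), bitDepth = 16L, channel = "marker")
  nucleus <- Micrograph(addNoise(nucClean), bitDepth = 16L, channel = "nucleus")

  list(marker = marker, nucleus = nucleus,
       truth = list(kind = "fluorescence", threshold = thr,
                    marker_sum = mSum, nucleus_sum = nSum,
                    rfi = if (nSum > 0) mSum / nSum else NA_real_,
                    centres = centres, positive = positive))
}
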