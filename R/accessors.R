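#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("bitDepth", "Micrograph", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setMethod("umPerPx", "Micrograph", function(x) x@umPerPx)

#' @rdname accessors
#' @param value positive numeric calibration in micrometres per pixel.
#' @export
setMethod("umPerPx<-", "Micrograph", function(x, value) {
  x@umPerPx <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("channelTag", "Micrograph", function(x) x@channel)

#' @rdname accessors
#' @export
setMethod("vertices", "Polyline", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("idv", "BandQuant", function(x) x@idv)

#' @rdname accessors
#' @export
setMethod("poolMean", "PooledEstimate", function(x) x@mean)

#' @rdname accessors
#' @export
setMethod("poolMean", "LevelSummary", function(x) x@mean)

#' @rdname accessors
#' @export
setMethod("poolVariance", "PooledEstimate", function(x) x@varianceOfMean)

#' @rdname accessors
#' @export
setMethod("poolVariance", "LevelSummary", function(x) x@variance)

#' @rdname accessors
#' @export
setMethod("poolWeights", "PooledEstimate", function(x) x@weights)

setMethod("show", "Micrograph", function(object) {
  cal <- if (is.na(object@umPerPx)) "uncalibrated"
         else sprintf("%.4g um/px", object@umPerPx)
  cat(sprintf("Micrograph %d x %d, %d-bit, channel '%s', %s\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              object@channel, cal))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "Polyline", function(object) {
  cat(sprintf("Polyline with %d vertices, length %.6g px\n",
              nrow(object@vertices), polylineLengthPx(object)))
})

setMethod("show", "NeuriteTree", function(object) {
  cat(sprintf("NeuriteTree: %d nodes, %d edges, longest path %.6g px\n",
              nrow(object@nodes), nrow(object@edges),
              longestPathLengthPx(object)))
  cat(sprintf("  soma anchor (%.1f, %.1f)\n",
              object@somaAnchor[1], object@somaAnchor[2]))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI [top=%d, left=%d, %d x %d]\n", object@top, object@left,
              object@height, object@width))
})

setMethod("show", "BandQuant", function(object) {
  cat(sprintf("BandQuant: IDV %.6g (background %.4g per px)\n",
              object@idv, object@backgroundMeanPerPx))
})

setMethod("show", "RFIResult", function(object) {
  cat(sprintf("RFIResult: marker %.6g / nucleus %.6g = RFI %.6g\n",
              object@markerSum, object@nucleusSum, object@rfi))
  cat(sprintf("  thresholds: marker %g, nucleus %g\n",
              object@markerThreshold, object@nucleusThreshold))
})

setMethod("show", "LevelSummary", function(object) {
  deg <- if (object@degenerate) " [degenerate variance]" else ""
  cat(sprintf("LevelSummary '%s': mean %.6g, variance %.6g, n %d%s\n",
              object@label, object@mean, object@variance, object@n, deg))
})

setMethod("show", "PooledEstimate", function(object) {
  cat(sprintf("PooledEstimate over %d levels: mean %.6g (SE %.4g)\n",
              object@nLevels, object@mean, sqrt(object@varianceOfMean)))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.5g, p = %.4g\n",
              object@dfBetween, object@dfWithin, object@fStatistic,
              object@pValue))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Determination coefficient: R^2 = %.4f (n = %d pairs)\n",
              object@rSquared, object@nPairs))
})
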