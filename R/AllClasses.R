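#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core image container
## ---------------------------------------------------------------------------

#' Micrograph: a 2-D grayscale intensity raster
#'
#' Container for a single-channel micrograph: a matrix of integer-valued
#' intensities together with its bit depth, a free-text channel tag and an
#' optional spatial calibration (micrometres per pixel). Coordinates follow
#' the (row, col) convention, 0-based externally in JSON files, 1-based as R
#' matrix indices; pixel centres sit at integer coordinates.
#'
#' @slot pixels numeric matrix of intensities, all within the bit-depth range.
#' @slot bitDepth integer, 8 or 16.
#' @slot channel character tag (e.g. "phase", "marker", "nucleus").
#' @slot umPerPx positive numeric or NA when the image is uncalibrated.
#'
#' @aliases Micrograph-class
#' @exportClass Micrograph
setClass("Micrograph",
  representation(
    pixels   = "matrix",
    bitDepth = "integer",
    channel  = "character",
    umPerPx  = "numeric"
  ),
  prototype(
    bitDepth = 16L,
    channel  = "gray",
    umPerPx  = NA_real_
  )
)

setValidity("Micrograph", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L) return("image must have height, width >= 1")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  if (any(!is.finite(px))) return("pixels contain non-finite values")
  rng <- 2^object@bitDepth - 1
  if (min(px) < 0 || max(px) > rng)
    return(sprintf("intensities outside [0, %d] for %d-bit image", rng, object@bitDepth))
  if (!is.na(object@umPerPx) && object@umPerPx <= 0)
    return("umPerPx must be positive when set")
  TRUE
})

#' Construct a Micrograph
#'
#' @param pixels numeric matrix of intensities.
#' @param bitDepth 8 or 16 (default 16).
#' @param channel free-text channel tag.
#' @param umPerPx optional spatial calibration in micrometres per pixel.
#' @return A \linkS4class{Micrograph}.
#' @examples
#' m <- Micrograph(matrix(0, 4, 4), bitDepth = 8)
#' dim(pixels(m))
#' @export
Micrograph <- function(pixels, bitDepth = 16L, channel = "gray", umPerPx = NA_real_) {
  new("Micrograph", pixels = pixels, bitDepth = as.integer(bitDepth),
      channel = channel, umPerPx = as.numeric(umPerPx))
}

## ---------------------------------------------------------------------------
## Geometry
## ---------------------------------------------------------------------------

#' Polyline: an ordered open chain of vertices
#'
#' Geometric trace of a neurite as an ordered list of (row, col) vertex
#' coordinates. Length is the sum of Euclidean segment lengths, measured on
#' the vertex coordinates, not on pixel counts.
#'
#' @slot vertices numeric matrix with two columns (row, col), >= 1 row;
#'   consecutive vertices are distinct.
#' @aliases Polyline-class
#' @exportClass Polyline
setClass("Polyline", representation(vertices = "matrix"))

setValidity("Polyline", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 1L) return("polyline needs at least one vertex")
  if (any(!is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(v) > 1L) {
    d <- diff(v)
    if (any(rowSums(d^2) == 0)) return("consecutive vertices must be distinct")
  }
  TRUE
})

#' @param vertices n x 2 numeric matrix of (row, col) coordinates.
#' @rdname Polyline-class
#' @examples
#' p <- Polyline(rbind(c(0, 0), c(3, 4)))
#' polylineLengthPx(p)
#' @export
Polyline <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  new("Polyline", vertices = matrix(as.numeric(vertices), ncol = 2L))
}

#' NeuriteTree: a rooted acyclic trace of a branched neurite
#'
#' Tree representation of a traced neurite: a soma anchor (the root, node 1),
#' a set of vertex coordinates, and parent -> child edges carrying Euclidean
#' segment weights. Neurite length is defined as the largest cumulative
#' root-to-leaf edge weight (the longest path is always chosen when a neurite
#' has several branches).
#'
#' @slot somaAnchor numeric length-2 (row, col) of the root.
#' @slot nodes n x 2 numeric matrix of vertex coordinates; node 1 is the root.
#' @slot edges data.frame with integer columns parent, child and numeric
#'   weight; the graph is connected and acyclic with node 1 as root.
#' @aliases NeuriteTree-class
#' @exportClass NeuriteTree
setClass("NeuriteTree",
  representation(somaAnchor = "numeric", nodes = "matrix", edges = "data.frame"))

setValidity("NeuriteTree", function(object) {
  n <- nrow(object@nodes)
  e <- object@edges
  if (length(object@somaAnchor) != 2L) return("somaAnchor must be (row, col)")
  if (n < 1L) return("tree needs at least one node")
  if (!all(c("parent", "child", "weight") %in% names(e)))
    return("edges must have parent, child, weight")
  if (nrow(e) != n - 1L) return("a tree on n nodes has n - 1 edges")
  if (n == 1L) return(TRUE)
  if (any(e$parent < 1L | e$parent > n | e$child < 1L | e$child > n))
    return("edge endpoints out of range")
  if (any(e$weight < 0)) return("edge weights must be non-negative")
  if (anyDuplicated(e$child) || any(e$child == 1L))
    return("every non-root node must have exactly one parent; root has none")
  ## connectivity: every node reaches the root through parent pointers
  parent <- integer(n); parent[e$child] <- e$parent
  for (v in seq_len(n)[-1L]) {
    u <- v; steps <- 0L
    while (u != 1L && steps <= n) { u <- parent[u]; steps <- steps + 1L }
    if (u != 1L) return("tree is not connected to the root")
  }
  TRUE
})

#' @param somaAnchor numeric (row, col) root coordinate.
#' @param nodes n x 2 matrix of node coordinates (node 1 = root).
#' @param edges data.frame(parent, child, weight).
#' @rdname NeuriteTree-class
#' @export
NeuriteTree <- function(somaAnchor, nodes, edges) {
  edges$parent <- as.integer(edges$parent)
  edges$child  <- as.integer(edges$child)
  edges$weight <- as.numeric(edges$weight)
  new("NeuriteTree", somaAnchor = as.numeric(somaAnchor),
      nodes = matrix(as.numeric(nodes), ncol = 2L), edges = edges)
}

## ---------------------------------------------------------------------------
## Densitometry
## ---------------------------------------------------------------------------

#' ROI: a rectangular pixel region
#'
#' Rectangular region of interest in image coordinates. \code{top} and
#' \code{left} are 1-based row/column indices of the upper-left pixel.
#'
#' @slot top,left integer upper-left corner (1-based).
#' @slot height,width integer extents, both >= 1.
#' @aliases ROI-class
#' @exportClass ROI
setClass("ROI", representation(top = "integer", left = "integer",
                               height = "integer", width = "integer"))

setValidity("ROI", function(object) {
  if (object@height < 1L || object@width < 1L) return("height and width must be >= 1")
  if (object@top < 1L || object@left < 1L) return("top and left must be >= 1")
  TRUE
})

#' @param top,left,height,width integers defining the rectangle.
#' @rdname ROI-class
#' @examples
#' ROI(5, 10, 20, 60)
#' @export
ROI <- function(top, left, height, width) {
  new("ROI", top = as.integer(top), left = as.integer(left),
      height = as.integer(height), width = as.integer(width))
}

#' BandQuant: background-subtracted integrated density of a blot band
#'
#' @slot idv numeric integrated density value: sum of in-ROI intensities minus
#'   the mean background per pixel times the ROI area. May be negative when
#'   noise pushes a faint band below its background.
#' @slot roi the band \linkS4class{ROI}.
#' @slot backgroundMeanPerPx numeric mean background intensity per pixel.
#' @aliases BandQuant-class
#' @exportClass BandQuant
setClass("BandQuant",
  representation(idv = "numeric", roi = "ROI", backgroundMeanPerPx = "numeric"))

#' RFIResult: suprathreshold marker intensity relative to the nucleus channel
#'
#' @slot markerSum non-negative cumulative suprathreshold intensity of the
#'   marker channel.
#' @slot nucleusSum positive cumulative suprathreshold intensity of the
#'   nucleus channel.
#' @slot rfi markerSum / nucleusSum.
#' @slot markerThreshold,nucleusThreshold thresholds actually applied.
#' @aliases RFIResult-class
#' @exportClass RFIResult
setClass("RFIResult",
  representation(markerSum = "numeric", nucleusSum = "numeric", rfi = "numeric",
                 markerThreshold = "numeric", nucleusThreshold = "numeric"))

setValidity("RFIResult", function(object) {
  if (object@markerSum < 0) return("markerSum must be >= 0")
  if (object@nucleusSum <= 0) return("nucleusSum must be positive")
  if (abs(object@rfi - object@markerSum / object@nucleusSum) >
      1e-9 * max(1, abs(object@rfi)))
    return("rfi must equal markerSum / nucleusSum")
  TRUE
})

## ---------------------------------------------------------------------------
## Aggregation
## ---------------------------------------------------------------------------

#' LevelSummary: (mean, variance, n) at one aggregation level
#'
#' @slot mean sample mean.
#' @slot variance unbiased sample variance; 0 when n = 1 (degenerate).
#' @slot n integer number of contributing measurements.
#' @slot label identifier of the level (picture id, replicate id, ...).
#' @slot degenerate TRUE when the variance is 0 by construction (n = 1 or all
#'   values identical) rather than estimated.
#' @aliases LevelSummary-class
#' @exportClass LevelSummary
setClass("LevelSummary",
  representation(mean = "numeric", variance = "numeric", n = "integer",
                 label = "character", degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("LevelSummary", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  if (!is.finite(object@mean)) return("mean must be finite")
  if (object@variance < 0) return("variance must be >= 0")
  TRUE
})

#' @param mean,variance,n,label,degenerate see slots.
#' @rdname LevelSummary-class
#' @export
LevelSummary <- function(mean, variance, n, label = "",
                         degenerate = (variance == 0)) {
  new("LevelSummary", mean = as.numeric(mean), variance = as.numeric(variance),
      n = as.integer(n), label = as.character(label),
      degenerate = isTRUE(degenerate))
}

#' PooledEstimate: a weighted pooled mean across aggregation levels
#'
#' @slot mean pooled mean.
#' @slot varianceOfMean non-negative variance of the pooled mean.
#' @slot nLevels integer number of pooled members.
#' @slot weights non-negative weights summing to 1.
#' @aliases PooledEstimate-class
#' @exportClass PooledEstimate
setClass("PooledEstimate",
  representation(mean = "numeric", varianceOfMean = "numeric",
                 nLevels = "integer", weights = "numeric"))

setValidity("PooledEstimate", function(object) {
  w <- object@weights
  if (length(w) != object@nLevels) return("one weight per level")
  if (any(w < 0)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1")
  if (object@varianceOfMean < 0) return("varianceOfMean must be >= 0")
  TRUE
})

#' AnovaResult: one-way analysis of variance
#'
#' @slot fStatistic non-negative F statistic.
#' @slot dfBetween,dfWithin integer degrees of freedom.
#' @slot pValue upper-tail p value from the F distribution.
#' @aliases AnovaResult-class
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(fStatistic = "numeric", dfBetween = "integer",
                 dfWithin = "integer", pValue = "numeric"))

setValidity("AnovaResult", function(object) {
  if (object@fStatistic < 0) return("F must be >= 0")
  if (object@dfBetween < 1L || object@dfWithin < 1L) return("dfs must be >= 1")
  if (object@pValue < 0 || object@pValue > 1) return("p must be in [0, 1]")
  TRUE
})

#' CorrelationResult: determination coefficient of a least-squares fit
#'
#' @slot rSquared R-squared in [0, 1].
#' @slot nPairs integer number of (x, y) pairs, >= 3.
#' @aliases CorrelationResult-class
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(rSquared = "numeric", nPairs = "integer"))

setValidity("CorrelationResult", function(object) {
  if (object@rSquared < 0 || object@rSquared > 1) return("R^2 must be in [0, 1]")
  if (object@nPairs < 3L) return("need at least 3 pairs")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-data specs
## ---------------------------------------------------------------------------

#' NeuronSceneSpec: parameters of a synthetic neuron scene
#'
#' Describes a dark-field scene of bright cell somata with piecewise-linear
#' neurites of known geometry, used as ground-truth test bed for the
#' morphometry chain.
#'
#' @slot imageHeightPx,imageWidthPx raster size.
#' @slot nCells number of cells (>= 0).
#' @slot somaRadiusPx soma disk radius in pixels.
#' @slot neuritesPerCell neurites per soma.
#' @slot neuriteLengthPxRange (min, max) geometric neurite length in pixels.
#' @slot branchProbability probability in [0, 1] that a neurite forks into a
#'   Y-branch; truth records the longest cumulative path.
#' @slot neuriteWidthPx drawn stroke width in pixels.
#' @slot foregroundIntensity,backgroundIntensity intensities in raster units;
#'   foreground must exceed background.
#' @slot noiseSd additive Gaussian noise standard deviation (raster units).
#' @slot umPerPx spatial calibration.
#' @aliases NeuronSceneSpec-class
#' @exportClass NeuronSceneSpec
setClass("NeuronSceneSpec",
  representation(imageHeightPx = "integer", imageWidthPx = "integer",
                 nCells = "integer", somaRadiusPx = "numeric",
                 neuritesPerCell = "integer", neuriteLengthPxRange = "numeric",
                 branchProbability = "numeric", neuriteWidthPx = "numeric",
                 foregroundIntensity = "numeric", backgroundIntensity = "numeric",
                 noiseSd = "numeric", umPerPx = "numeric"))

setValidity("NeuronSceneSpec", function(object) {
  r <- object@neuriteLengthPxRange
  if (length(r) != 2L || r[1] > r[2] || any(r <= 0))
    return("neuriteLengthPxRange must be (min, max) with 0 < min <= max")
  if (object@foregroundIntensity <= object@backgroundIntensity)
    return("foregroundIntensity must exceed backgroundIntensity")
  if (object@nCells < 0L || object@neuritesPerCell < 0L)
    return("counts must be >= 0")
  if (object@branchProbability < 0 || object@branchProbability > 1)
    return("branchProbability must be in [0, 1]")
  if (object@somaRadiusPx <= 0 || object@neuriteWidthPx <= 0 ||
      object@umPerPx <= 0)
    return("somaRadiusPx, neuriteWidthPx, umPerPx must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@imageHeightPx < 1L || object@imageWidthPx < 1L)
    return("image size must be >= 1")
  TRUE
})

#' @param imageHeightPx,imageWidthPx,nCells,somaRadiusPx,neuritesPerCell see slots.
#' @param neuriteLengthPxRange,branchProbability,neuriteWidthPx see slots.
#' @param foregroundIntensity,backgroundIntensity,noiseSd,umPerPx see slots.
#' @rdname NeuronSceneSpec-class
#' @export
neuronSceneSpec <- function(imageHeightPx = 384L, imageWidthPx = 384L,
                            nCells = 5L, somaRadiusPx = 8,
                            neuritesPerCell = 2L,
                            neuriteLengthPxRange = c(30, 55),
                            branchProbability = 0.3, neuriteWidthPx = 2.5,
                            foregroundIntensity = 40000,
                            backgroundIntensity = 6000,
                            noiseSd = 400, umPerPx = 0.323) {
  new("NeuronSceneSpec",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx), nCells = as.integer(nCells),
      somaRadiusPx = somaRadiusPx, neuritesPerCell = as.integer(neuritesPerCell),
      neuriteLengthPxRange = as.numeric(neuriteLengthPxRange),
      branchProbability = branchProbability, neuriteWidthPx = neuriteWidthPx,
      foregroundIntensity = foregroundIntensity,
      backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
      umPerPx = umPerPx)
}

#' BlotSpec: parameters of a synthetic Western-blot film
#'
#' Each lane carries two bands (target over loading control), modelled as
#' isotropic Gaussian bumps of known analytic integrated volume, rendered in
#' film polarity (dark bands on a light background) over a linear background
#' ramp plus noise.
#'
#' @slot lanes numeric matrix with columns target, loading: per-lane band
#'   amplitudes (raster units, >= 0).
#' @slot bandSigmaPx Gaussian band radius parameter.
#' @slot lanePitchPx horizontal centre-to-centre lane spacing; must exceed
#'   4 * bandSigmaPx so bands do not overlap.
#' @slot backgroundLevel film background intensity (light).
#' @slot backgroundGradient linear intensity ramp per pixel along columns.
#' @slot noiseSd additive Gaussian noise SD.
#' @aliases BlotSpec-class
#' @exportClass BlotSpec
setClass("BlotSpec",
  representation(lanes = "matrix", bandSigmaPx = "numeric",
                 lanePitchPx = "integer", backgroundLevel = "numeric",
                 backgroundGradient = "numeric", noiseSd = "numeric"))

setValidity("BlotSpec", function(object) {
  if (ncol(object@lanes) != 2L || nrow(object@lanes) < 1L)
    return("lanes must be an n x 2 matrix (target, loading amplitudes)")
  if (any(object@lanes < 0)) return("amplitudes must be >= 0")
  if (object@bandSigmaPx <= 0) return("bandSigmaPx must be positive")
  if (object@lanePitchPx <= 4 * object@bandSigmaPx)
    return("lanePitchPx must exceed 4 * bandSigmaPx (bands must not overlap)")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @param lanes n x 2 matrix or list of c(target, loading) amplitudes.
#' @param bandSigmaPx,lanePitchPx,backgroundLevel,backgroundGradient,noiseSd see slots.
#' @rdname BlotSpec-class
#' @export
blotSpec <- function(lanes, bandSigmaPx = 12, lanePitchPx = 100L,
                     backgroundLevel = 52000, backgroundGradient = 2,
                     noiseSd = 0) {
  if (is.list(lanes)) lanes <- do.call(rbind, lanes)
  new("BlotSpec", lanes = matrix(as.numeric(lanes), ncol = 2L),
      bandSigmaPx = bandSigmaPx, lanePitchPx = as.integer(lanePitchPx),
      backgroundLevel = backgroundLevel,
      backgroundGradient = backgroundGradient, noiseSd = noiseSd)
}

#' FluorPairSpec: parameters of a synthetic two-channel fluorescence pair
#'
#' A nucleus channel of \code{nNuclei} stained disks and a marker channel in
#' which a fraction of the same objects is positive, with exact ground-truth
#' suprathreshold sums recorded at generation time.
#'
#' @slot nNuclei number of nuclei.
#' @slot nucleusRadiusPx disk radius.
#' @slot markerFractionPositive fraction of objects positive for the marker.
#' @slot markerAmplitude,nucleusAmplitude peak intensities; both must exceed
#'   thresholdTruth so positive objects count.
#' @slot thresholdTruth the threshold at which ground-truth sums are taken.
#' @slot noiseSd additive Gaussian noise SD.
#' @slot imageShape (height, width).
#' @aliases FluorPairSpec-class
#' @exportClass FluorPairSpec
setClass("FluorPairSpec",
  representation(nNuclei = "integer", nucleusRadiusPx = "numeric",
                 markerFractionPositive = "numeric", markerAmplitude = "numeric",
                 nucleusAmplitude = "numeric", thresholdTruth = "numeric",
                 noiseSd = "numeric", imageShape = "integer"))

setValidity("FluorPairSpec", function(object) {
  if (object@nNuclei < 0L) return("nNuclei must be >= 0")
  if (object@markerFractionPositive < 0 || object@markerFractionPositive > 1)
    return("markerFractionPositive must be in [0, 1]")
  if (object@markerAmplitude <= object@thresholdTruth)
    return("markerAmplitude must exceed thresholdTruth")
  if (object@nucleusAmplitude <= object@thresholdTruth)
    return("nucleusAmplitude must exceed thresholdTruth")
  if (object@nucleusRadiusPx <= 0) return("nucleusRadiusPx must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    return("imageShape must be (height, width) >= 1")
  TRUE
})

#' @param nNuclei,nucleusRadiusPx,markerFractionPositive see slots.
#' @param markerAmplitude,nucleusAmplitude,thresholdTruth,noiseSd,imageShape see slots.
#' @rdname FluorPairSpec-class
#' @export
fluorPairSpec <- function(nNuclei = 12L, nucleusRadiusPx = 7,
                          markerFractionPositive = 0.5,
                          markerAmplitude = 30000, nucleusAmplitude = 25000,
                          thresholdTruth = 5000, noiseSd = 0,
                          imageShape = c(192L, 192L)) {
  new("FluorPairSpec", nNuclei = as.integer(nNuclei),
      nucleusRadiusPx = nucleusRadiusPx,
      markerFractionPositive = markerFractionPositive,
      markerAmplitude = markerAmplitude, nucleusAmplitude = nucleusAmplitude,
      thresholdTruth = thresholdTruth, noiseSd = noiseSd,
      imageShape = as.integer(imageShape))
}

#' HierarchySpec: parameters of a nested measurement hierarchy
#'
#' Emulates the sampling design of neurite-length studies: independent
#' experiments performed in duplicate, several pictures per replicate, and
#' 15-30 individual measurements per picture, with Gaussian variance
#' components between experiments, between pictures, and within pictures.
#'
#' @slot nExperiments,replicatesPerExperiment,picturesPerReplicate counts (>= 1).
#' @slot measurementsPerPictureRange integer (min, max) measurements per picture.
#' @slot grandMean true population mean of the measured quantity.
#' @slot sdBetweenExperiments,sdBetweenPictures,sdWithinPicture Gaussian
#'   component standard deviations (>= 0).
#' @aliases HierarchySpec-class
#' @exportClass HierarchySpec
setClass("HierarchySpec",
  representation(nExperiments = "integer", replicatesPerExperiment = "integer",
                 picturesPerReplicate = "integer",
                 measurementsPerPictureRange = "integer",
                 grandMean = "numeric", sdBetweenExperiments = "numeric",
                 sdBetweenPictures = "numeric", sdWithinPicture = "numeric"))

setValidity("HierarchySpec", function(object) {
  if (object@nExperiments < 1L || object@replicatesPerExperiment < 1L ||
      object@picturesPerReplicate < 1L)
    return("all counts must be >= 1")
  r <- object@measurementsPerPictureRange
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
    return("measurementsPerPictureRange must be (min, max) with 1 <= min <= max")
  if (object@sdBetweenExperiments < 0 || object@sdBetweenPictures < 0 ||
      object@sdWithinPicture < 0)
    return("sd components must be >= 0")
  TRUE
})

#' @param nExperiments,replicatesPerExperiment,picturesPerReplicate see slots.
#' @param measurementsPerPictureRange,grandMean see slots.
#' @param sdBetweenExperiments,sdBetweenPictures,sdWithinPicture see slots.
#' @rdname HierarchySpec-class
#' @export
hierarchySpec <- function(nExperiments = 3L, replicatesPerExperiment = 2L,
                          picturesPerReplicate = 5L,
                          measurementsPerPictureRange = c(15L, 30L),
                          grandMean = 60, sdBetweenExperiments = 5,
                          sdBetweenPictures = 4, sdWithinPicture = 12) {
  new("HierarchySpec", nExperiments = as.integer(nExperiments),
      replicatesPerExperiment = as.integer(replicatesPerExperiment),
      picturesPerReplicate = as.integer(picturesPerReplicate),
      measurementsPerPictureRange = as.integer(measurementsPerPictureRange),
      grandMean = grandMean, sdBetweenExperiments = sdBetweenExperiments,
      sdBetweenPictures = sdBetweenPictures, sdWithinPicture = sdWithinPicture)
}
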