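#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the core containers: \code{pixels} returns the intensity
#' matrix of a \linkS4class{Micrograph}; \code{bitDepth} its bit depth;
#' \code{umPerPx} its calibration; \code{vertices} the coordinate matrix of a
#' \linkS4class{Polyline}; \code{idv} the integrated density of a
#' \linkS4class{BandQuant}; \code{rfi} is documented with
#' \code{\link{rfi,Micrograph,Micrograph-method}}.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))

#' @rdname accessors
#' @export
setGeneric("umPerPx<-", function(x, value) standardGeneric("umPerPx<-"))

#' @rdname accessors
#' @export
setGeneric("channelTag", function(x) standardGeneric("channelTag"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("idv", function(x) standardGeneric("idv"))

#' @rdname accessors
#' @export
setGeneric("poolMean", function(x) standardGeneric("poolMean"))

#' @rdname accessors
#' @export
setGeneric("poolVariance", function(x) standardGeneric("poolVariance"))

#' @rdname accessors
#' @export
setGeneric("poolWeights", function(x) standardGeneric("poolWeights"))

#' Relative fluorescence intensity of a marker channel vs a nucleus channel
#'
#' @param marker marker-channel \linkS4class{Micrograph}.
#' @param nucleus nucleus-channel \linkS4class{Micrograph} of the same shape.
#' @param ... further arguments passed to methods.
#' @return An \linkS4class{RFIResult}.
#' @export
setGeneric("rfi", function(marker, nucleus, ...) standardGeneric("rfi"))
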