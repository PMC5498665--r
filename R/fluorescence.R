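#' Threshold policy for fluorescence quantification
#'
#' The reference procedure uses a pre-determined fixed threshold per channel;
#' Otsu's method is available as a fallback when no value is supplied.
#'
#' @param mode "fixed" or "otsu".
#' @param fixed_value the pre-determined threshold; required iff
#'   \code{mode = "fixed"}.
#' @return A validated policy list.
#' @export
thresholdPolicy <- function(mode = c("fixed", "otsu"), fixed_value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(fixed_value) || !is.finite(fixed_value)))
    stop("fixed mode requires a finite fixed_value")
  if (mode == "otsu" && !is.null(fixed_value))
    stop("fixed_value must be absent in otsu mode")
  list(mode = mode, fixed_value = fixed_value)
}

#' Select an intensity threshold for a micrograph
#'
#' Fixed mode returns the pre-determined value unchanged; Otsu mode returns
#' the cut maximizing the between-class variance of the intensity histogram.
#' A constant image has no separable classes and is an error in Otsu mode.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param policy output of \code{\link{thresholdPolicy}}.
#' @return Numeric threshold on the image's intensity scale.
#' @export
selectThreshold <- function(image, policy) {
  stopifnot(is(image, "Micrograph"))
  if (policy$mode == "fixed") return(as.numeric(policy$fixed_value))
  otsu_threshold(as.vector(image@pixels))
}

#' Cumulative suprathreshold intensity
#'
#' The relative fluorescence intensity of a channel is the cumulative sum of
#' the value of each pixel strictly above the threshold ("above" is read
#' strictly, and qualifying pixels contribute their raw value, not the excess
#' over the threshold). Returns 0 when no pixel qualifies.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param threshold numeric cut.
#' @return Non-negative numeric sum.
#' @examples
#' m <- Micrograph(matrix(c(1, 7, 5, 3), 2, 2), bitDepth = 8)
#' suprathresholdSum(m, 4)  # 5 + 7 = 12
#' @export
suprathresholdSum <- function(image, threshold) {
  stopifnot(is(image, "Micrograph"), is.finite(threshold))
  px <- image@pixels
  sum(px[px > threshold])
}

#' @describeIn rfi Suprathreshold marker intensity normalized to the nucleus
#'   channel: both channels are thresholded and summed independently by the
#'   same procedure, and the marker sum is divided by the nucleus sum (which
#'   corrects for cell abundance). A zero nucleus sum leaves no normalizer
#'   and is an error.
#' @param policy threshold policy applied to the marker channel.
#' @param nucleus_policy threshold policy for the nucleus channel; defaults
#'   to \code{policy}.
#' @export
setMethod("rfi", signature("Micrograph", "Micrograph"),
  function(marker, nucleus, policy, nucleus_policy = policy) {
    if (!identical(dim(marker@pixels), dim(nucleus@pixels)))
      stop("marker and nucleus images must share the same shape")
    mt <- selectThreshold(marker, policy)
    nt <- selectThreshold(nucleus, nucleus_policy)
    ms <- suprathresholdSum(marker, mt)
    ns <- suprathresholdSum(nucleus, nt)
    if (ns <= 0)
      stop("zero nucleus suprathreshold signal: no normalizer")
    new("RFIResult", markerSum = ms, nucleusSum = ns, rfi = ms / ns,
        markerThreshold = mt, nucleusThreshold = nt)
  })
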