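#' Integrated density of a blot band with local background subtraction
#'
#' Sums the intensities of all pixels in a user-defined band ROI and
#' subtracts the average background — the mean pixel intensity in an
#' equally-sized area near the ROI — scaled by the band ROI area:
#' \code{idv = sum(band) - mean(background) * area(band)}. Subtracting the
#' per-pixel background mean times the area (rather than a single scalar from
#' a summed intensity) keeps the quantity dimensionally consistent; it is the
#' standard gel-densitometry reading of background subtraction.
#'
#' Digitized X-ray films carry signal as dark bands on a light background, so
#' by default intensities are inverted (\code{max_range - pixel}) before
#' summation; set \code{invert = FALSE} for signal-bright images.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param band_roi \linkS4class{ROI} covering the band.
#' @param background_roi \linkS4class{ROI} of identical dimensions near the
#'   band; must not overlap it.
#' @param invert invert film polarity before summation (default TRUE).
#' @return A \linkS4class{BandQuant}; its \code{idv} may be negative when
#'   noise pushes a faint band below the background estimate.
#' @export
integratedDensity <- function(image, band_roi, background_roi, invert = TRUE) {
  stopifnot(is(image, "Micrograph"), is(band_roi, "ROI"),
            is(background_roi, "ROI"))
  px <- image@pixels
  .check_roi_inside <- function(r, what) {
    if (r@top + r@height - 1L > nrow(px) || r@left + r@width - 1L > ncol(px))
      stop(what, " ROI out of image bounds")
  }
  .check_roi_inside(band_roi, "band")
  .check_roi_inside(background_roi, "background")
  if (band_roi@height != background_roi@height ||
      band_roi@width != background_roi@width)
    stop("background ROI dimensions must match the band ROI")
  if (roisOverlap(band_roi, background_roi))
    stop("background ROI must not overlap the band ROI")
  if (invert) px <- (2^image@bitDepth - 1) - px
  sub <- function(r) px[r@top:(r@top + r@height - 1L),
                        r@left:(r@left + r@width - 1L)]
  bgMean <- mean(sub(background_roi))
  val <- sum(sub(band_roi)) - bgMean * band_roi@height * band_roi@width
  new("BandQuant", idv = val, roi = band_roi, backgroundMeanPerPx = bgMean)
}

## TRUE when two ROIs share any pixel.
roisOverlap <- function(a, b) {
  !(a@top + a@height - 1L < b@top || b@top + b@height - 1L < a@top ||
    a@left + a@width - 1L < b@left || b@left + b@width - 1L < a@left)
}

#' Enforce identical ROI dimensions across all bands
#'
#' The same ROI dimensions must be used for all bands in all experiments;
#' this validator passes the list through unchanged iff every ROI shares the
#' dimensions of the first, and otherwise fails naming the offending indices.
#'
#' @param rois non-empty list of \linkS4class{ROI}.
#' @return The input list, invisibly validated.
#' @export
enforceUniformRoi <- function(rois) {
  if (length(rois) == 0L) stop("ROI list is empty")
  h <- rois[[1]]@height; w <- rois[[1]]@width
  bad <- which(vapply(rois, function(r) r@height != h || r@width != w,
                      logical(1)))
  if (length(bad))
    stop("ROI dimension mismatch at index ", paste(bad, collapse = ", "),
         ": all bands must use ", h, " x ", w)
  rois
}

#' Normalize a target band to its loading control
#'
#' The IDV of a band of interest is divided by the IDV of its lane's loading
#' control (e.g. beta-actin) to correct for unequal protein loading. A
#' non-positive loading-control IDV makes the lane unusable; a negative
#' target IDV propagates as a negative ratio with a warning.
#'
#' @param target \linkS4class{BandQuant} of the band of interest.
#' @param loading \linkS4class{BandQuant} of the loading control.
#' @return Numeric ratio \code{target / loading}.
#' @export
normalizeBand <- function(target, loading) {
  stopifnot(is(target, "BandQuant"), is(loading, "BandQuant"))
  if (loading@idv <= 0)
    stop("loading-control IDV is not positive; lane unusable")
  if (target@idv < 0)
    warning("negative target IDV: reporting a negative ratio")
  target@idv / loading@idv
}

#' Fold change of loading-normalized ratios versus a reference condition
#'
#' Divides every condition's ratio by the reference condition's (e.g. the
#' control without RA), so the reference maps to exactly 1; this second
#' normalization absorbs the overall scale variability of each independent
#' experiment.
#'
#' @param ratios named numeric vector of loading-normalized ratios.
#' @param reference name of the reference condition; must be present with a
#'   positive ratio.
#' @return Named numeric vector of fold changes; \code{[reference] == 1}.
#' @examples
#' foldChange(c(ctl = 2, a = 4), "ctl")
#' @export
foldChange <- function(ratios, reference) {
  if (!reference %in% names(ratios))
    stop("reference condition '", reference, "' missing from ratios")
  ref <- ratios[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference ratio must be positive")
  ratios / ref
}
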