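#' Generate a synthetic Western-blot film with known band volumes
#'
#' Renders one lane per row of the spec's amplitude matrix, each lane carrying
#' a target band (upper row) and a loading-control band (lower row). Bands
#' are isotropic Gaussian bumps of known analytic integrated volume. The
#' image uses film polarity: signal is dark on a light background, so the
#' rendered pixel value is \code{backgroundLevel + gradient * (col - 1) -
#' sum(bumps) + noise}, clipped to the 16-bit range. Ground truth records each
#' band's true integrated signal (the discrete sum of its analytic bump over
#' the raster, i.e. the IDV an ideal densitometer would measure after
#' inversion and background subtraction) and the true target/loading ratio
#' per lane.
#'
#' @param spec a \linkS4class{BlotSpec}.
#' @param seed integer seed.
#' @return List with \code{image} (\linkS4class{Micrograph}) and \code{truth}
#'   (list: \code{kind = "blot"}, per-lane records with band centres, sigma,
#'   \code{target_idv}, \code{loading_idv}, \code{ratio}).
#' @examples
#' b <- generateBlotImage(blotSpec(rbind(c(8000, 6000), c(4000, 6000))), seed = 1)
#' b$truth$lanes[[1]]$ratio
#' @export
generateBlotImage <- function(spec, seed = 0L) {
  stopifnot(is(spec, "BlotSpec"))
  validObject(spec)
  with_seed(seed, .generate_blot(spec))
}

.generate_blot <- function(spec) {
  nl <- nrow(spec@lanes)
  pitch <- spec@lanePitchPx
  w <- pitch * nl
  ## vertical layout sized so that an ROI of half-width 4*sigma fits above
  ## each band (the default background placement) without touching the other
  ## band's bump
  half <- ceiling(4 * spec@bandSigmaPx)
  side <- 2L * half + 1L
  rowT <- half + side + 2
  rowL <- rowT + side + 2L * half + 2
  h <- as.integer(rowL + half + 2)
  if ((rowL - rowT) <= 4 * spec@bandSigmaPx)
    stop("overlapping bands: lane_pitch_px too small for band_sigma_px")
  maxAmp <- max(spec@lanes)
  if (spec@backgroundLevel - maxAmp < 0)
    stop("band amplitude exceeds background level: film would saturate black")
  if (spec@backgroundLevel + spec@backgroundGradient * (w - 1) > 2^16 - 1)
    stop("background ramp exceeds the 16-bit range")

  bump <- matrix(0, h, w)
  cols <- seq_len(w); rows <- seq_len(h)
  lanes <- vector("list", nl)
  s2 <- 2 * spec@bandSigmaPx^2
  for (j in seq_len(nl)) {
    cx <- pitch * (j - 0.5) + 0.5
    addBand <- function(cy, A) {
      if (A == 0) return(0)
      g <- A * exp(-outer((rows - cy)^2, (cols - cx)^2, "+") / s2)
      bump <<- bump + g
      sum(g)
    }
    tI <- addBand(rowT, spec@lanes[j, 1])
    lI <- addBand(rowL, spec@lanes[j, 2])
    lanes[[j]] <- list(lane = j, centre_col = cx,
                       target_row = rowT, loading_row = rowL,
                       sigma_px = spec@bandSigmaPx,
                       target_idv = tI, loading_idv = lI,
                       ratio = if (lI > 0) tI / lI else NA_real_)
  }

  px <- spec@backgroundLevel +
        spec@backgroundGradient * matrix(cols - 1, h, w, byrow = TRUE) - bump
  if (spec@noiseSd > 0) px <- px + rnorm(h * w, 0, spec@noiseSd)
  img <- Micrograph(quantize_raster(px, 16L), bitDepth = 16L, channel = "film")
  list(image = img,
       truth = list(kind = "blot", lane_pitch_px = pitch,
                    image_shape = c(h, w), lanes = lanes))
}

#' Default band and background ROIs for a generated blot
#'
#' Places, for every lane of a generated blot, a band ROI of half-width
#' \code{4 * sigma} centred on each band and a background ROI of identical
#' dimensions directly above it at one ROI-height offset (the default "area
#' near the ROI" policy). All ROIs share identical dimensions.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generateBlotImage}}.
#' @return List per lane with \code{target}, \code{target_bg},
#'   \code{loading}, \code{loading_bg} \linkS4class{ROI} objects.
#' @export
defaultBlotRois <- function(truth) {
  stopifnot(identical(truth$kind, "blot"))
  sig <- truth$lanes[[1]]$sigma_px
  half <- ceiling(4 * sig)
  side <- 2L * half + 1L
  lapply(truth$lanes, function(ln) {
    mk <- function(cy) {
      top <- as.integer(round(cy)) - half
      left <- as.integer(round(ln$centre_col)) - half
      list(band = ROI(top, left, side, side),
           bg = ROI(top - side, left, side, side))
    }
    t <- mk(ln$target_row); l <- mk(ln$loading_row)
    list(lane = ln$lane, target = t$band, target_bg = t$bg,
         loading = l$band, loading_bg = l$bg)
  })
}
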