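#' Filter parameters for the neurite enhancement chain
#'
#' The enhancement pipeline has a fixed order: Gaussian smoothing to remove
#' noise, a Laplacian high-pass to pick out thin bright structures, a median
#' filter to suppress salt noise in the response, then binarization. Kernel
#' sizes are deliberately the smallest standard choices consistent with that
#' role.
#'
#' @param gaussian_sigma_px Gaussian smoothing sigma in pixels (default 1).
#' @param laplace_neighborhood "4-connected" (default) or "8-connected"
#'   discrete Laplacian stencil.
#' @param median_window_px odd window size >= 3 for the median filter.
#' @param edge_threshold "otsu" (default) for automatic binarization of the
#'   absolute Laplacian response, or a fixed numeric cut on the normalized
#'   [0, 1] response.
#' @return A list of validated filter parameters.
#' @export
filterParams <- function(gaussian_sigma_px = 1.0,
                         laplace_neighborhood = c("4-connected", "8-connected"),
                         median_window_px = 3L,
                         edge_threshold = "otsu") {
  laplace_neighborhood <- match.arg(laplace_neighborhood)
  stopifnot(gaussian_sigma_px > 0)
  median_window_px <- as.integer(median_window_px)
  if (median_window_px < 3L || median_window_px %% 2L == 0L)
    stop("median_window_px must be an odd integer >= 3")
  if (!identical(edge_threshold, "otsu") && !is.numeric(edge_threshold))
    stop("edge_threshold must be \"otsu\" or a fixed numeric value")
  list(gaussian_sigma_px = gaussian_sigma_px,
       laplace_neighborhood = laplace_neighborhood,
       median_window_px = median_window_px,
       edge_threshold = edge_threshold)
}

#' Enhance neurites in a phase-contrast micrograph
#'
#' Applies the fixed chain Gaussian smooth -> Laplacian high-pass -> median
#' filter -> binarization and returns a boolean edge map of the same shape as
#' the input. The binarization acts on the absolute Laplacian response
#' normalized to [0, 1]; a constant image therefore yields an all-false map.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param params output of \code{\link{filterParams}}.
#' @return Logical matrix of the input shape; TRUE marks enhanced edges.
#' @examples
#' sc <- generateNeuronScene(neuronSceneSpec(nCells = 1L, noiseSd = 0), seed = 1)
#' edges <- enhanceNeurites(sc$image)
#' mean(edges)
#' @export
enhanceNeurites <- function(image, params = filterParams()) {
  stopifnot(is(image, "Micrograph"))
  px <- image@pixels
  if (any(!is.finite(px))) stop("image contains non-finite pixels")
  x <- px / (2^image@bitDepth - 1)

  sm <- EBImage::gblur(x, sigma = params$gaussian_sigma_px)
  kern <- if (params$laplace_neighborhood == "4-connected")
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  else
    matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)
  lap <- abs(EBImage::filter2(sm, kern))

  mx <- max(lap)
  if (mx == 0) return(matrix(FALSE, nrow(px), ncol(px)))
  resp <- lap / mx
  radius <- (params$median_window_px - 1L) %/% 2L
  resp <- as.matrix(EBImage::medianFilter(resp, radius))

  thr <- if (identical(params$edge_threshold, "otsu")) {
    if (length(unique(as.vector(resp))) < 2L) return(matrix(FALSE, nrow(px), ncol(px)))
    otsu_threshold(round(as.vector(resp) * 65535)) / 65535
  } else as.numeric(params$edge_threshold)
  resp > thr
}

#' Superimpose an edge map on the original micrograph in blue
#'
#' Returns an RGB raster equal to the grayscale original replicated over the
#' three channels, except that edge pixels are rendered in a fixed pure blue.
#' Non-edge pixels are bit-identical to the grayscale replication.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param edges logical matrix of the same shape.
#' @return Numeric array h x w x 3 in [0, 1].
#' @export
overlayEdges <- function(image, edges) {
  stopifnot(is(image, "Micrograph"), is.logical(edges))
  if (!identical(dim(image@pixels), dim(edges)))
    stop("image and edge map shapes differ")
  g <- image@pixels / (2^image@bitDepth - 1)
  out <- array(g, dim = c(dim(g), 3L))
  r <- out[, , 1]; gg <- out[, , 2]; b <- out[, , 3]
  r[edges] <- 0; gg[edges] <- 0; b[edges] <- 1
  out[, , 1] <- r; out[, , 2] <- gg; out[, , 3] <- b
  out
}

#' Write an RGB overlay to PNG
#'
#' @param overlay array from \code{\link{overlayEdges}}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeOverlay <- function(overlay, path) {
  png::writePNG(overlay, path)
  invisible(path)
}
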