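#' Read a grayscale micrograph from TIFF or PNG
#'
#' Reads an 8- or 16-bit grayscale image into a \linkS4class{Micrograph}.
#' Multi-channel files are rejected; images are stored as integer intensities
#' on the native bit-depth scale.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param channel channel tag to record.
#' @param umPerPx optional calibration in micrometres per pixel.
#' @return A \linkS4class{Micrograph}.
#' @export
readMicrograph <- function(path, channel = "gray", umPerPx = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    bits <- 16L
    raw <- raw * (2^16 - 1)
  } else stop("unsupported image format: ", ext)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] != 1L) stop("expected a single-channel grayscale image")
    raw <- raw[, , 1L]
  }
  Micrograph(round(raw), bitDepth = bits, channel = channel, umPerPx = umPerPx)
}

#' Write a Micrograph as 16-bit (or 8-bit) grayscale TIFF
#'
#' @param x a \linkS4class{Micrograph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMicrograph <- function(x, path) {
  stopifnot(is(x, "Micrograph"))
  rng <- 2^x@bitDepth - 1
  tiff::writeTIFF(x@pixels / rng, path, bits.per.sample = x@bitDepth)
  invisible(path)
}

#' Read polyline annotations from JSON
#'
#' The annotation format is
#' \code{{"picture_id": str, "um_per_px": float, "polylines": [[[r,c],...]]}}
#' with 0-based row-major pixel coordinates.
#'
#' @param path JSON annotation file.
#' @return list with \code{picture_id}, \code{um_per_px} and a list of
#'   \linkS4class{Polyline} objects (coordinates converted to 1-based).
#' @export
readAnnotations <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- lapply(j$polylines, function(pl)
    Polyline(do.call(rbind, lapply(pl, function(v)
      c(v[[1]], v[[2]]))) + 1))
  list(picture_id = j$picture_id, um_per_px = j$um_per_px,
       polylines = polys)
}

#' Write polyline annotations to JSON
#'
#' @param polylines list of \linkS4class{Polyline}.
#' @param picture_id picture identifier.
#' @param um_per_px calibration.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(polylines, picture_id, um_per_px, path) {
  j <- list(picture_id = picture_id, um_per_px = um_per_px,
            polylines = lapply(polylines, function(p) unname(vertices(p) - 1)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a densitometry ROI manifest from JSON
#'
#' Format: \code{{"image": str, "bands": [{"label": str, "roi":
#' [top,left,height,width], "background_roi": [...], "lane": str,
#' "is_loading_control": bool}]}} with 0-based top/left.
#'
#' @param path JSON manifest file.
#' @return list with \code{image} and a data.frame-like list of band entries
#'   whose ROIs are \linkS4class{ROI} objects (1-based).
#' @export
readRoiManifest <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  bands <- lapply(j$bands, function(b) {
    r <- unlist(b$roi); g <- unlist(b$background_roi)
    list(label = b$label, lane = b$lane,
         is_loading_control = isTRUE(b$is_loading_control),
         roi = ROI(r[1] + 1, r[2] + 1, r[3], r[4]),
         background_roi = ROI(g[1] + 1, g[2] + 1, g[3], g[4]))
  })
  list(image = j$image, bands = bands)
}

## md5 checksums of a set of files, named by basename (manifest plumbing).
file_checksums <- function(paths) {
  sums <- tools::md5sum(paths)
  names(sums) <- basename(paths)
  as.list(sums)
}
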