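#' Euclidean length of a polyline in pixels
#'
#' Neurite length is the Euclidean distance, or a chained combination of
#' Euclidean distances, between the cell body and the end of the neurite —
#' computed on the vertex coordinates, never on pixel counts. A single-vertex
#' polyline has length 0.
#'
#' @param p a \linkS4class{Polyline}.
#' @return Non-negative numeric length in pixels.
#' @examples
#' polylineLengthPx(Polyline(rbind(c(0, 0), c(3, 4))))  # 5
#' @export
polylineLengthPx <- function(p) {
  stopifnot(is(p, "Polyline"))
  segsum(p@vertices)
}

#' Longest root-to-leaf path length of a neurite tree in pixels
#'
#' When a neurite has several branches the longest path is always chosen:
#' the returned length is the maximum, over all leaves, of the cumulative
#' edge weight from the soma anchor (root) to that leaf.
#'
#' @param t a \linkS4class{NeuriteTree}.
#' @return Non-negative numeric length in pixels.
#' @examples
#' tr <- NeuriteTree(c(0, 0), rbind(c(0, 0), c(20, 0), c(50, 0), c(40, 30)),
#'   data.frame(parent = c(1, 2, 2), child = c(2, 3, 4), weight = c(20, 30, 50)))
#' longestPathLengthPx(tr)  # 20 + max(30, 50) = 70
#' @export
longestPathLengthPx <- function(t) {
  stopifnot(is(t, "NeuriteTree"))
  n <- nrow(t@nodes)
  if (n == 0L) stop("empty tree")
  if (n == 1L) return(0)
  depth <- numeric(n)
  ## edges validated parent-before-child reachable; accumulate by repeated
  ## relaxation in topological order via parent pointers
  parent <- integer(n); wt <- numeric(n)
  parent[t@edges$child] <- t@edges$parent
  wt[t@edges$child] <- t@edges$weight
  done <- c(TRUE, rep(FALSE, n - 1L))
  order <- seq_len(n)[-1L]
  while (length(order)) {
    ready <- order[done[parent[order]]]
    if (!length(ready)) stop("tree is not rooted at node 1")
    depth[ready] <- depth[parent[ready]] + wt[ready]
    done[ready] <- TRUE
    order <- setdiff(order, ready)
  }
  leaves <- setdiff(seq_len(n), t@edges$parent)
  max(depth[leaves])
}

#' Convert a pixel length to micrometres
#'
#' Lengths in pixels are calibrated against the microscope's length bar:
#' a bar of known physical length spanning a known number of pixels fixes
#' \code{um_per_px}, and a measured length is \code{length_px * um_per_px}.
#'
#' @param length_px non-negative pixel length.
#' @param um_per_px positive calibration factor (micrometres per pixel).
#' @return Length in micrometres.
#' @examples
#' calibrateLength(200, 0.5)  # 100
#' @export
calibrateLength <- function(length_px, um_per_px) {
  if (missing(um_per_px) || is.null(um_per_px) || is.na(um_per_px))
    stop("missing calibration: um_per_px is required")
  stopifnot(length_px >= 0, um_per_px > 0, is.finite(um_per_px))
  length_px * um_per_px
}

#' Scale calibration from a length bar
#'
#' @param bar_um physical bar length in micrometres.
#' @param bar_px bar span in pixels.
#' @return \code{um_per_px}.
#' @examples
#' scaleFromBar(100, 250)  # 0.4
#' @export
scaleFromBar <- function(bar_um, bar_px) {
  stopifnot(bar_um > 0, bar_px > 0)
  bar_um / bar_px
}

#' Measure all neurites of one picture
#'
#' Applies the longest-path rule (for \linkS4class{NeuriteTree} inputs) or
#' the chained Euclidean length (for \linkS4class{Polyline} inputs), then
#' calibrates each length to micrometres and records the number of
#' measurements taken.
#'
#' @param traces list of \linkS4class{NeuriteTree} and/or
#'   \linkS4class{Polyline} objects; must be non-empty.
#' @param um_per_px positive calibration factor.
#' @param picture_id picture identifier.
#' @return A list with \code{picture_id}, \code{lengths_um} and \code{n}.
#' @examples
#' measurePicture(list(Polyline(rbind(c(0, 0), c(3, 4)))), 1, "p1")
#' @export
measurePicture <- function(traces, um_per_px, picture_id = "picture") {
  if (length(traces) == 0L) stop("no measurements for picture ", picture_id)
  lengths_px <- vapply(traces, function(x) {
    if (is(x, "NeuriteTree")) longestPathLengthPx(x)
    else if (is(x, "Polyline")) polylineLengthPx(x)
    else stop("traces must be NeuriteTree or Polyline objects")
  }, numeric(1))
  list(picture_id = picture_id,
       lengths_um = vapply(lengths_px, calibrateLength, numeric(1),
                           um_per_px = um_per_px),
       n = length(lengths_px))
}
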