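## Automated tracing: skeletonize the enhanced edge map, anchor skeleton
## components at their soma attachment points, and read off rooted trees.
## Annotation mode (operator polylines) remains the reference path for
## exactness; tracing is the automated stand-in.

## Guo-Hall two-subiteration thinning of a logical matrix, vectorized over
## whole passes. Chosen over Zhang-Suen, whose parallel deletion erases
## even-width diagonal bands completely.
guo_hall_thin <- function(mask) {
  m <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
    rok <- rs >= 1L & rs <= h; cok <- cs >= 1L & cs <= w
    out[rok, cok] <- x[rs[rok], cs[cok]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      C <- (1L - p2) * pmax(p3, p4) + (1L - p4) * pmax(p5, p6) +
           (1L - p6) * pmax(p7, p8) + (1L - p8) * pmax(p9, p2)
      n1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      n2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      n <- pmin(n1, n2)
      mm <- if (pass == 1L) pmax(pmax(p6, p7), 1L - p9) * p8
            else pmax(pmax(p2, p3), 1L - p5) * p4
      cond <- m == 1L & C == 1L & n >= 2L & n <= 3L & mm == 0L
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

#' Trace neurite trees from an enhanced edge map
#'
#' Skeletonizes the boolean edge map (Guo-Hall thinning), removes skeleton
#' pixels inside a margin around each soma (the soma's own edge ring is not a
#' neurite), anchors every remaining skeleton component at its nearest soma
#' attachment point, and converts the component's geodesic shortest-path tree
#' into a \linkS4class{NeuriteTree}. Pixel chains between branch points are
#' simplified to polylines before their Euclidean length is summed, and the
#' small gap between the soma boundary and the first retained skeleton pixel
#' is re-added as a radial root segment. Trees whose longest path falls below
#' \code{min_length_px} are discarded, as are components not attached to any
#' soma.
#'
#' @param edges logical edge map from \code{\link{enhanceNeurites}}.
#' @param soma_mask logical raster marking soma disks; must contain at least
#'   one component.
#' @param min_length_px minimum longest-path length to keep (default 10).
#' @param soma_margin_px extra clearance around each soma within which
#'   skeleton pixels are attributed to the soma rim (default 4).
#' @param image optional \linkS4class{Micrograph} the edge map came from;
#'   when supplied, leaf endpoints are refined on the half-maximum stroke
#'   mask of the Gaussian-smoothed image, whose rounded end cap is symmetric
#'   (longitudinal overshoot equals transverse half-width), which locates
#'   stroke ends more accurately than the Laplacian band.
#' @return List of \linkS4class{NeuriteTree} objects.
#' @export
traceNeurites <- function(edges, soma_mask, min_length_px = 10,
                          soma_margin_px = 4, image = NULL) {
  stopifnot(is.logical(edges), is.logical(soma_mask))
  if (!identical(dim(edges), dim(soma_mask)))
    stop("edge map and soma mask shapes differ")
  if (!any(soma_mask))
    stop("no soma component found in soma_mask")
  if (!any(edges)) return(list())

  lab <- label8(soma_mask)
  ns <- max(lab)
  cent <- matrix(NA_real_, ns, 2); rad <- numeric(ns)
  for (i in seq_len(ns)) {
    idx <- which(lab == i, arr.ind = TRUE)
    cent[i, ] <- colMeans(idx)
    rad[i] <- sqrt(nrow(idx) / pi)
  }

  sk <- guo_hall_thin(edges)
  pix <- which(sk, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(pix))
  for (i in seq_len(ns)) {
    d <- sqrt((pix[, 1] - cent[i, 1])^2 + (pix[, 2] - cent[i, 2])^2)
    keep <- keep & d > rad[i] + soma_margin_px
  }
  sk2 <- matrix(FALSE, nrow(sk), ncol(sk))
  sk2[pix[keep, , drop = FALSE]] <- TRUE
  if (!any(sk2)) return(list())

  ## parallel thinning can nick a continuous band into pieces across narrow
  ## diagonal runs; clusters closer than bridge_px are re-joined (distinct
  ## neurites stay farther apart than that)
  comp <- .bridge_clusters(label8(sk2), bridge_px = 4)
  dm <- as.matrix(EBImage::distmap(edges * 1))
  sm <- NULL; smBg <- NULL
  if (!is.null(image)) {
    stopifnot(is(image, "Micrograph"))
    sm <- as.matrix(EBImage::gblur(image@pixels / (2^image@bitDepth - 1),
                                   sigma = 1))
    smBg <- stats::median(sm)
  }
  trees <- list()
  for (ci in seq_len(max(comp))) {
    p <- which(comp == ci, arr.ind = TRUE)
    if (nrow(p) < 2L) next
    ## nearest soma and attachment distance
    gap <- vapply(seq_len(ns), function(i)
      min(sqrt((p[, 1] - cent[i, 1])^2 + (p[, 2] - cent[i, 2])^2)) - rad[i],
      numeric(1))
    si <- which.min(gap)
    if (gap[si] > soma_margin_px + 4) next   # unattached fragment
    if (!is.null(sm)) {
      ## half-max stroke mask of the smoothed image, local to this component,
      ## with a sub-pixel transverse half-width measured on the smoothed
      ## intensity profile (the integer distance map quantizes badly on
      ## bands only a few pixels wide)
      fg <- stats::median(sm[p])
      thrHalf <- (fg + smBg) / 2
      band <- sm > thrHalf
      bandDist <- as.matrix(EBImage::distmap(band * 1))
      halfWidth <- .subpixel_halfwidth(sm, thrHalf, p)
      if (is.na(halfWidth))
        halfWidth <- max(0.75, stats::median(bandDist[p]) - 0.5)
    } else {
      band <- edges
      bandDist <- dm
      halfWidth <- max(0.75, stats::median(dm[p]) - 0.5)
    }
    tree <- .component_tree(p, cent[si, ], rad[si], band, halfWidth, bandDist)
    if (!is.null(tree) && longestPathLengthPx(tree) >= min_length_px)
      trees[[length(trees) + 1L]] <- tree
  }
  trees
}

## Build a NeuriteTree from one skeleton component's pixel set, rooted at the
## pixel nearest the soma centre, with a radial anchor segment back to the
## soma boundary. Thinning erodes the rounded end cap of the edge band by
## about its half-width, so each leaf is extended along its local direction
## for as long as the band continues, minus that half-width.
.component_tree <- function(p, centre, radius, edges = NULL, halfWidth = 0,
                            bandDist = NULL) {
  n <- nrow(p)
  key <- p[, 1] * 1e6 + p[, 2]
  idx <- seq_len(n)
  ## 8-neighbour edges
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(off))) {
    nb <- cbind(p[, 1] + off[k, 1], p[, 2] + off[k, 2])
    m <- match(nb[, 1] * 1e6 + nb[, 2], key)
    hit <- which(!is.na(m))
    if (length(hit)) {
      ef <- c(ef, idx[hit]); et <- c(et, m[hit])
      ew <- c(ew, rep(sqrt(sum(off[k, ]^2)), length(hit)))
    }
  }
  if (!length(ef)) return(NULL)
  br <- .cluster_bridges(p)
  if (!is.null(br)) {
    ef <- c(ef, as.integer(br[, 1])); et <- c(et, as.integer(br[, 2]))
    ew <- c(ew, br[, 3])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew), directed = FALSE,
    vertices = data.frame(name = idx))
  droot <- sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2)
  root <- which.min(droot)
  sp <- igraph::shortest_paths(g, from = as.character(root),
                               to = igraph::V(g), predecessors = TRUE)
  pred <- as.integer(names(sp$predecessors))
  vnames <- as.integer(names(igraph::V(g)))
  parent <- rep(NA_integer_, n)
  parent[vnames] <- pred[seq_along(vnames)]
  parent[root] <- 0L
  reached <- !is.na(parent)
  if (sum(reached) < 2L) return(NULL)

  ## tree degrees over reached pixels
  nchild <- tabulate(parent[reached & parent > 0L], nbins = n)
  keep <- reached & (idx == root | nchild != 1L)  # root, leaves, forks
  keptIdx <- which(keep)

  ## each kept node's depth is the length of its full root-to-node pixel
  ## chain after smoothing and simplification; measuring whole chains (with
  ## fixed endpoints) straightens detour bulges that skeletonization leaves
  ## around acute forks, which per-segment measurement cannot see. Edge
  ## weights are depth differences, so path sums equal whole-chain lengths.
  nodesCoord <- list(p[root, ])
  nodeMap <- integer(n); nodeMap[root] <- 1L
  depth <- numeric(n)
  edgesParent <- integer(0); edgesChild <- integer(0); edgesW <- numeric(0)
  ## process kept nodes in increasing geodesic order so parents exist first
  dist_g <- igraph::distances(g, v = as.character(root))
  dvec <- rep(Inf, n); dvec[vnames] <- as.numeric(dist_g)[seq_along(vnames)]
  for (v in keptIdx[order(dvec[keptIdx])]) {
    if (v == root) next
    chain <- v
    u <- parent[v]
    prevKept <- 0L
    while (u != 0L) {
      if (keep[u] && prevKept == 0L) prevKept <- u
      chain <- c(chain, u)
      u <- parent[u]
    }
    if (prevKept == 0L) next
    coords <- p[rev(chain), , drop = FALSE]    # full root -> v pixel chain
    simp <- simplify_polyline(
      .repair_corners(smooth_chain(coords), halfWidth, bandDist), eps = 2.5)
    depth[v] <- segsum(simp)
    nodesCoord[[length(nodesCoord) + 1L]] <- p[v, ]
    nodeMap[v] <- length(nodesCoord)
    edgesParent <- c(edgesParent, nodeMap[prevKept])
    edgesChild <- c(edgesChild, nodeMap[v])
    edgesW <- c(edgesW, max(0.01, depth[v] - depth[prevKept]))
  }
  if (!length(edgesParent)) return(NULL)

  ## leaf extension into the eroded end cap: follow the band geodesically
  ## from each leaf (within +/- 60 degrees of the outgoing direction) and
  ## stop one half-width short of the farthest reachable band pixel
  if (!is.null(edges) && halfWidth > 0) {
    mapped <- which(nodeMap > 0L)
    isLeaf <- vapply(mapped, function(v)
      v != root && !(nodeMap[v] %in% edgesParent), logical(1))
    for (v in mapped[isLeaf]) {
      back <- v
      for (s in 1:4) if (parent[back] > 0L) back <- parent[back]
      dir <- p[v, ] - p[back, ]
      nr <- sqrt(sum(dir^2))
      if (nr == 0) next
      dir <- dir / nr
      ex <- .extend_leaf(edges, p[v, ], dir, halfWidth)
      if (is.null(ex)) next
      if (ex$length > 0) {
        nodesCoord[[length(nodesCoord) + 1L]] <- ex$endpoint
        edgesParent <- c(edgesParent, nodeMap[v])
        edgesChild <- c(edgesChild, length(nodesCoord))
        edgesW <- c(edgesW, ex$length)
      } else {
        ## retraction: shorten the leaf's incoming edge and pull the node
        ## back along the outgoing direction
        ei <- which(edgesChild == nodeMap[v])
        if (length(ei) == 1L) {
          take <- min(-ex$length, edgesW[ei] - 0.1)
          if (take > 0) {
            edgesW[ei] <- edgesW[ei] - take
            nodesCoord[[nodeMap[v]]] <- p[v, ] - take * dir
          }
        }
      }
    }
  }

  nodes <- do.call(rbind, nodesCoord)
  rootPx <- p[root, ]
  gap <- sqrt(sum((rootPx - centre)^2)) - radius
  if (gap > 0.5) {
    anchor <- centre + radius * (rootPx - centre) / sqrt(sum((rootPx - centre)^2))
    nodes <- rbind(anchor, nodes)
    edges <- data.frame(parent = c(1L, edgesParent + 1L),
                        child = c(2L, edgesChild + 1L),
                        weight = c(gap, edgesW))
    NeuriteTree(anchor, nodes, edges)
  } else {
    NeuriteTree(rootPx, nodes,
                data.frame(parent = edgesParent, child = edgesChild,
                           weight = edgesW))
  }
}

## Re-label clusters, merging any pair whose closest pixels are within
## bridge_px of each other. Returns an updated label matrix; merged clusters
## share one label. The subsequent graph construction adds the physical
## bridge edges itself (via .cluster_bridges).
.bridge_clusters <- function(lab, bridge_px = 4) {
  k <- max(lab)
  if (k < 2L) return(lab)
  pts <- lapply(seq_len(k), function(i) which(lab == i, arr.ind = TRUE))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ## cheap bbox rejection before the exact pass
      if (min(pts[[j]][, 1]) > max(pts[[i]][, 1]) + bridge_px ||
          min(pts[[i]][, 1]) > max(pts[[j]][, 1]) + bridge_px ||
          min(pts[[j]][, 2]) > max(pts[[i]][, 2]) + bridge_px ||
          min(pts[[i]][, 2]) > max(pts[[j]][, 2]) + bridge_px) next
      d2 <- outer(pts[[i]][, 1], pts[[j]][, 1], "-")^2 +
            outer(pts[[i]][, 2], pts[[j]][, 2], "-")^2
      if (min(d2) <= bridge_px^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

## Extra graph edges joining nearest pixel pairs of the thinning-nicked
## sub-clusters inside one (bridged) component.
.cluster_bridges <- function(p, bridge_px = 4) {
  key <- p[, 1] * 1e6 + p[, 2]
  sub <- matrix(FALSE, max(p[, 1]) + 1L, max(p[, 2]) + 1L)
  sub[p] <- TRUE
  lab <- label8(sub)
  ids <- lab[p]
  k <- max(ids)
  if (k < 2L) return(NULL)
  bridges <- NULL
  ## connect every cluster to its nearest neighbour cluster; iterate until
  ## one component remains
  repeat {
    groups <- split(seq_len(nrow(p)), ids)
    if (length(groups) < 2L) break
    gi <- groups[[1L]]
    best <- NULL
    for (g in groups[-1L]) {
      d2 <- outer(p[gi, 1], p[g, 1], "-")^2 + outer(p[gi, 2], p[g, 2], "-")^2
      w <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
      cand <- c(gi[w[1]], g[w[2]], sqrt(min(d2)))
      if (is.null(best) || cand[3] < best[3]) best <- cand
    }
    if (best[3] > bridge_px + 1e-9) break   # remaining pieces too far: stop
    bridges <- rbind(bridges, best)
    ids[ids == ids[best[2]]] <- ids[best[1]]
  }
  bridges
}

## Sub-pixel transverse half-width of a band: at sampled skeleton pixels,
## march perpendicular to the local tangent on the bilinearly interpolated
## smoothed image to the half-max crossings on both sides; returns the
## median half-span, or NA when no sample yields both crossings.
.subpixel_halfwidth <- function(sm, thr, p, n_samples = 15L) {
  n <- nrow(p)
  take <- p[unique(round(seq(1, n, length.out = min(n_samples, n)))), ,
            drop = FALSE]
  widths <- c()
  for (i in seq_len(nrow(take))) {
    q <- take[i, ]
    nb <- p[abs(p[, 1] - q[1]) <= 3 & abs(p[, 2] - q[2]) <= 3, , drop = FALSE]
    if (nrow(nb) < 3L) next
    tangent <- stats::prcomp(nb)$rotation[, 1]
    perp <- c(-tangent[2], tangent[1])
    crossing <- function(sgn) {
      prev <- bilinear_at(sm, q[1], q[2])
      if (prev <= thr) return(NA_real_)
      for (s in seq(0.25, 4, by = 0.25)) {
        val <- bilinear_at(sm, q[1] + sgn * s * perp[1],
                           q[2] + sgn * s * perp[2])
        if (val < thr)
          return((s - 0.25) + 0.25 * (prev - thr) / max(prev - val, 1e-9))
        prev <- val
      }
      NA_real_
    }
    s1 <- crossing(1); s2 <- crossing(-1)
    if (!is.na(s1) && !is.na(s2)) widths <- c(widths, (s1 + s2) / 2)
  }
  if (!length(widths)) return(NA_real_)
  stats::median(widths)
}

## Where branch bands merge, the skeleton rounds and displaces corners onto
## the wedge bisector, so a measured chain S-detours around the true branch
## point. Repair by corner reconstruction: find high-curvature apexes on the
## chain, merge apexes whose windows overlap (the two opposing turns of an
## S-detour collapse into one window), and rebuild each window as the sharp
## intersection of the flanking straight directions — which for a genuine
## corner and for a detour alike sits at the true turn point.
.repair_corners <- function(coords, halfWidth, bandDist = NULL,
                            turn_deg = 20) {
  lag <- 4L
  n <- nrow(coords)
  if (n < 3L * lag) return(coords)
  ang <- rep(0, n)
  for (i in (lag + 1L):(n - lag)) {
    u <- coords[i, ] - coords[i - lag, ]
    v <- coords[i + lag, ] - coords[i, ]
    ca <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    ang[i] <- acos(min(1, max(-1, ca)))
  }
  apex <- which(ang > turn_deg * pi / 180)
  if (!length(apex)) return(coords)
  R <- as.integer(ceiling(2 * max(halfWidth, 1.5) + 2))
  groups <- split(apex, cumsum(c(1, diff(apex) > R)))
  for (gi in rev(seq_along(groups))) {       # right-to-left keeps indices valid
    g <- groups[[gi]]
    a <- max(min(g) - R, lag + 1L)
    b <- min(max(g) + R, nrow(coords) - lag)
    if (b - a < 2L) next
    A <- coords[a, ]; B <- coords[b, ]
    dirA <- A - coords[a - lag, ]
    dirB <- coords[b + lag, ] - B
    M <- cbind(dirA, dirB)
    if (abs(det(M)) < 1e-8) next             # flanks parallel: not a corner
    ts <- solve(M, B - A)
    lens <- ts * c(sqrt(sum(dirA^2)), sqrt(sum(dirB^2)))
    if (any(ts < 0) || any(lens > 1.5 * (b - a))) next
    X <- A + ts[1] * dirA
    ## a band-merge detour only ever adds length, so a reconstruction is
    ## accepted only when it shortens the window
    oldLen <- segsum(coords[a:b, , drop = FALSE])
    newLen <- sqrt(sum((X - A)^2)) + sqrt(sum((B - X)^2))
    if (newLen >= oldLen) next
    coords <- rbind(coords[seq_len(a), , drop = FALSE], X,
                    coords[b:nrow(coords), , drop = FALSE])
  }
  coords
}

## Geodesic leaf extension: BFS over band pixels in a local window around
## the leaf, restricted to the forward cone, returning the extra length to
## the farthest reachable pixel minus the band half-width.
.extend_leaf <- function(band, leaf, dir, halfWidth, maxr = 12L) {
  h <- nrow(band); w <- ncol(band)
  r0 <- max(1L, leaf[1] - maxr); r1 <- min(h, leaf[1] + maxr)
  c0 <- max(1L, leaf[2] - maxr); c1 <- min(w, leaf[2] + maxr)
  sub <- band[r0:r1, c0:c1, drop = FALSE]
  pts <- which(sub, arr.ind = TRUE)
  if (nrow(pts) < 2L) return(NULL)
  pts[, 1] <- pts[, 1] + r0 - 1L; pts[, 2] <- pts[, 2] + c0 - 1L
  key <- pts[, 1] * 1e6 + pts[, 2]
  start <- match(leaf[1] * 1e6 + leaf[2], key)
  if (is.na(start)) return(NULL)
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(off))) {
    m <- match((pts[, 1] + off[k, 1]) * 1e6 + (pts[, 2] + off[k, 2]), key)
    hit <- which(!is.na(m))
    if (length(hit)) {
      ef <- c(ef, hit); et <- c(et, m[hit])
      ew <- c(ew, rep(sqrt(sum(off[k, ]^2)), length(hit)))
    }
  }
  if (!length(ef)) return(NULL)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(pts))))
  d <- as.numeric(igraph::distances(g, v = as.character(start)))
  d <- d[match(seq_len(nrow(pts)), as.integer(names(igraph::V(g))))]
  vec <- cbind(pts[, 1] - leaf[1], pts[, 2] - leaf[2])
  nr <- sqrt(rowSums(vec^2))
  cosang <- (vec[, 1] * dir[1] + vec[, 2] * dir[2]) / pmax(nr, 1e-9)
  ## forward cone, near-straight geodesics only (a zigzagging geodesic means
  ## the walk left the end cap and wandered into a merged-band blob), and an
  ## overall cap: erosion cannot exceed the end-cap half-width by much
  ok <- is.finite(d) & (nr < 1.5 | (cosang > 0.5 & d <= 1.3 * nr))
  if (!any(ok)) return(NULL)
  far <- which(ok)[which.max(d[ok])]
  ## sub-pixel model of the end cap: Gaussian blurring pulls the level set
  ## of a rounded cap inward by ~sigma^2/(2a) (curvature flow, sigma = 1
  ## here), so the band protrudes about a - 1/(2a) beyond the geometric
  ## stroke end, with a the transverse half-width
  a <- max(0.75, halfWidth)
  ext <- d[far] - (a - 1 / (2 * a))
  if (ext <= 0.25) return(NULL)
  u <- if (nr[far] > 1e-9) vec[far, ] / nr[far] else dir
  list(length = ext, endpoint = leaf + ext * u)
}

#' Match traced trees to ground-truth neurites by anchor proximity
#'
#' Validation helper: pairs every ground-truth neurite of a generated scene
#' with the traced tree whose soma anchor is nearest to the true anchor, and
#' tabulates true versus traced longest-path lengths.
#'
#' @param trees list of \linkS4class{NeuriteTree} from
#'   \code{\link{traceNeurites}}.
#' @param truth \code{truth} element of \code{\link{generateNeuronScene}}.
#' @return data.frame with columns \code{true_length_px},
#'   \code{traced_length_px}, \code{anchor_dist_px} (NA rows for unmatched
#'   truth neurites).
#' @export
matchTracedToTruth <- function(trees, truth) {
  stopifnot(identical(truth$kind, "neurites"))
  anchors <- t(vapply(trees, function(t) t@somaAnchor, numeric(2)))
  out <- lapply(truth$neurites, function(nt) {
    if (length(trees) == 0L)
      return(data.frame(true_length_px = nt$length_px,
                        traced_length_px = NA_real_, anchor_dist_px = NA_real_))
    d <- sqrt((anchors[, 1] - nt$anchor[1])^2 + (anchors[, 2] - nt$anchor[2])^2)
    j <- which.min(d)
    data.frame(true_length_px = nt$length_px,
               traced_length_px = longestPathLengthPx(trees[[j]]),
               anchor_dist_px = d[j])
  })
  do.call(rbind, out)
}
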