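#' Generate a synthetic neuron scene with ground-truth neurite geometry
#'
#' Renders a dark-field scene of bright cell somata (anti-aliased disks) with
#' piecewise-linear neurites drawn as anti-aliased strokes, plus additive
#' Gaussian noise clipped to the bit-depth range. The geometric truth is the
#' vertex polyline, not the raster: every neurite's vertex list, soma anchor
#' and true longest-path length (in px and um) are recorded. A Y-branch
#' replaces the distal part of a neurite with two arms; the recorded length
#' follows the longest cumulative root-to-leaf path.
#'
#' Cells are placed so that their neurite territories cannot overlap; if the
#' requested geometry cannot fit within the retry budget the generator fails
#' naming the spec field to shrink.
#'
#' @param spec a \linkS4class{NeuronSceneSpec}.
#' @param seed integer seed; identical (spec, seed) pairs give bit-identical
#'   output.
#' @return A list with elements \code{image} (\linkS4class{Micrograph}),
#'   \code{truth} (list: \code{kind = "neurites"}, per-neurite records with
#'   \code{cell}, \code{anchor}, \code{paths} (root-to-leaf vertex matrices),
#'   \code{length_px}, \code{length_um}; plus soma centres and radius),
#'   \code{somaMask} and \code{neuriteMask} (logical rasters of the drawn,
#'   noise-free geometry).
#' @examples
#' sc <- generateNeuronScene(neuronSceneSpec(nCells = 2L, noiseSd = 0), seed = 1)
#' length(sc$truth$neurites)
#' @export
generateNeuronScene <- function(spec, seed = 0L) {
  stopifnot(is(spec, "NeuronSceneSpec"))
  validObject(spec)
  with_seed(seed, .generate_neuron_scene(spec))
}

.generate_neuron_scene <- function(spec) {
  h <- spec@imageHeightPx; w <- spec@imageWidthPx
  maxLen <- spec@neuriteLengthPxRange[2]
  territory <- spec@somaRadiusPx + maxLen + spec@neuriteWidthPx + 2

  centres <- .place_centres(spec@nCells, h, w, territory)
  if (is.null(centres))
    stop("scene overflow: cannot place ", spec@nCells, " non-overlapping cells; ",
         "shrink n_cells, neurite_length_px_range or soma_radius_px, ",
         "or enlarge image_height_px/image_width_px")

  somaCov <- matrix(0, h, w)
  neuriteCov <- matrix(0, h, w)
  neurites <- list()

  ## neurites of one cell must stay clear of each other, or their rendered
  ## strokes (and the enhancement filter's response bands) would merge;
  ## resample the whole cell until every pair keeps its distance
  clearance <- spec@neuriteWidthPx + 7

  for (i in seq_len(spec@nCells)) {
    ctr <- centres[i, ]
    somaCov <- pmax(somaCov, disk_coverage(h, w, ctr, spec@somaRadiusPx))
    if (spec@neuritesPerCell == 0L) next
    cellNeurites <- NULL
    for (attempt in 1:40) {
      cand <- list()
      base <- runif(1, 0, 2 * pi)
      sep <- 2 * pi / spec@neuritesPerCell
      for (k in seq_len(spec@neuritesPerCell)) {
        theta <- base + (k - 1) * sep + runif(1, -0.25, 0.25) * sep
        L <- runif(1, spec@neuriteLengthPxRange[1],
                   spec@neuriteLengthPxRange[2])
        branched <- runif(1) < spec@branchProbability
        cand[[k]] <- c(.grow_neurite(ctr, spec@somaRadiusPx, theta, L,
                                     branched),
                       list(branched = branched))
      }
      if (.neurites_clear(cand, clearance)) { cellNeurites <- cand; break }
    }
    if (is.null(cellNeurites))
      stop("scene overflow: cannot keep ", spec@neuritesPerCell,
           " neurites per cell non-overlapping; shrink neurites_per_cell ",
           "or branch_probability, or widen the angular budget by reducing ",
           "neurite_length_px_range")
    for (nt in cellNeurites) {
      for (v in nt$paths) {
        for (s in seq_len(nrow(v) - 1L))
          neuriteCov <- pmax(neuriteCov,
            segment_coverage(h, w, v[s, ], v[s + 1L, ], spec@neuriteWidthPx))
      }
      neurites[[length(neurites) + 1L]] <- list(
        cell = i, anchor = nt$anchor, branched = nt$branched,
        paths = nt$paths,
        length_px = max(vapply(nt$paths, segsum, numeric(1))),
        length_um = max(vapply(nt$paths, segsum, numeric(1))) * spec@umPerPx)
    }
  }

  cov <- pmax(somaCov, neuriteCov)
  px <- spec@backgroundIntensity +
        (spec@foregroundIntensity - spec@backgroundIntensity) * cov
  if (spec@noiseSd > 0) px <- px + rnorm(h * w, 0, spec@noiseSd)
  img <- Micrograph(quantize_raster(px, 16L), bitDepth = 16L,
                    channel = "phase", umPerPx = spec@umPerPx)
  truth <- list(kind = "neurites",
                soma_centres = centres, soma_radius_px = spec@somaRadiusPx,
                um_per_px = spec@umPerPx, neurites = neurites)
  list(image = img, truth = truth,
       somaMask = somaCov > 0.5, neuriteMask = neuriteCov > 0.5)
}

## Sequential rejection placement of cell centres with pairwise separation
## 2 * territory; NULL when the budget is exhausted.
.place_centres <- function(n, h, w, territory) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo <- territory + 1
  if (h - territory < lo || w - territory < lo) return(NULL)
  ## best-candidate sampling: each cell takes, of 80 uniform draws, the one
  ## farthest from the cells already placed; restart if even that violates
  ## the separation constraint
  for (restart in 1:40) {
    centres <- matrix(NA_real_, n, 2)
    centres[1, ] <- c(runif(1, lo, h - territory), runif(1, lo, w - territory))
    ok <- TRUE
    for (i in seq_len(n)[-1L]) {
      cand <- cbind(runif(80, lo, h - territory), runif(80, lo, w - territory))
      prev <- centres[seq_len(i - 1L), , drop = FALSE]
      minDist <- apply(cand, 1L, function(q)
        min(sqrt(rowSums(sweep(prev, 2, q)^2))))
      best <- which.max(minDist)
      if (minDist[best] < 2 * territory) { ok <- FALSE; break }
      centres[i, ] <- cand[best, ]
    }
    if (ok) return(centres)
  }
  NULL
}

## Points sampled along a polyline at ~1 px spacing.
.path_points <- function(v, step = 1) {
  out <- list()
  for (s in seq_len(nrow(v) - 1L)) {
    a <- v[s, ]; b <- v[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    out[[s]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

## TRUE when every pair of distinct neurites keeps at least `clearance`
## between their sampled centrelines.
.neurites_clear <- function(neurites, clearance) {
  if (length(neurites) < 2L) return(TRUE)
  pts <- lapply(neurites, function(nt)
    do.call(rbind, lapply(nt$paths, .path_points)))
  for (i in seq_len(length(pts) - 1L)) {
    for (j in (i + 1L):length(pts)) {
      d2 <- outer(pts[[i]][, 1], pts[[j]][, 1], "-")^2 +
            outer(pts[[i]][, 2], pts[[j]][, 2], "-")^2
      if (min(d2) < clearance^2) return(FALSE)
    }
  }
  TRUE
}

## Grow one neurite of total longest-path length L starting on the soma
## boundary at angle theta. Returns the anchor and the root-to-leaf paths
## (one for an unbranched neurite, two for a Y-branch). Segment lengths are
## exact, so the vertex-wise segment sum of the longest path equals L.
.grow_neurite <- function(centre, somaR, theta, L, branched,
                          stem_frac = 0.4, short_arm_frac = 0.35) {
  anchor <- centre + somaR * c(sin(theta), cos(theta))
  wiggle_path <- function(start, dir, len, nseg) {
    steps <- rep(len / nseg, nseg)
    v <- matrix(NA_real_, nseg + 1L, 2); v[1L, ] <- start
    for (s in seq_len(nseg)) {
      dir <- dir + runif(1, -0.2, 0.2)
      v[s + 1L, ] <- v[s, ] + steps[s] * c(sin(dir), cos(dir))
    }
    list(v = v, dir = dir)
  }
  if (!branched) {
    p <- wiggle_path(anchor, theta, L, 4L)
    return(list(anchor = anchor, paths = list(p$v)))
  }
  stem <- wiggle_path(anchor, theta, L * stem_frac, 2L)
  fork <- stem$v[nrow(stem$v), ]
  split <- runif(1, 0.35, 0.6)
  armA <- wiggle_path(fork, stem$dir + split, L * (1 - stem_frac), 3L)
  armB <- wiggle_path(fork, stem$dir - split, L * short_arm_frac, 2L)
  list(anchor = anchor,
       paths = list(rbind(stem$v, armA$v[-1L, , drop = FALSE]),
                    rbind(stem$v, armB$v[-1L, , drop = FALSE])))
}
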