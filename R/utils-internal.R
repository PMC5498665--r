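## Internal helpers shared across modules.

## Run `expr` under a local RNG stream seeded with `seed`; the caller's
## .Random.seed is untouched, so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Otsu threshold on integer-valued intensities: exhaustive maximization of
## between-class variance over the observed histogram. Returns a cut value t
## such that classes are {<= t} and {> t}.
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  lev <- sort(unique(v))
  if (length(lev) < 2L)
    stop("Otsu threshold undefined: image has a single intensity level")
  cnt <- tabulate(match(v, lev), nbins = length(lev))
  n <- length(v)
  w  <- cumsum(cnt)[-length(lev)]          # class-0 counts at each cut
  s  <- cumsum(cnt * lev)[-length(lev)]    # class-0 intensity sums
  tot <- sum(cnt * lev)
  mu0 <- s / w
  mu1 <- (tot - s) / (n - w)
  between <- (w / n) * (1 - w / n) * (mu0 - mu1)^2
  i <- which.max(between)
  ## report the midpoint of the gap between the two classes, so the cut
  ## separates them symmetrically (classes are {<= t} and {> t})
  (lev[i] + lev[i + 1L]) / 2
}

## Clip to bit range and round to integer raster values.
quantize_raster <- function(px, bitDepth) {
  rng <- 2^bitDepth - 1
  px <- round(px)
  px[px < 0] <- 0
  px[px > rng] <- rng
  px
}

## Anti-aliased disk stamp: returns coverage in [0, 1] for the given canvas
## size, centre (row, col) and radius; coverage ramps linearly over 1 px.
disk_coverage <- function(h, w, centre, radius) {
  r0 <- max(1L, floor(centre[1] - radius - 1)); r1 <- min(h, ceiling(centre[1] + radius + 1))
  c0 <- max(1L, floor(centre[2] - radius - 1)); c1 <- min(w, ceiling(centre[2] + radius + 1))
  cov <- matrix(0, h, w)
  if (r0 > r1 || c0 > c1) return(cov)
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - centre[1])^2, (cols - centre[2])^2, "+"))
  cov[rows, cols] <- pmin(1, pmax(0, radius + 0.5 - d))
  cov
}

## Distance from pixel centres to a segment a-b (rows/cols), restricted to a
## bounding box; used for anti-aliased stroke rendering.
segment_coverage <- function(h, w, a, b, width) {
  half <- width / 2
  pad <- half + 1.5
  r0 <- max(1L, floor(min(a[1], b[1]) - pad)); r1 <- min(h, ceiling(max(a[1], b[1]) + pad))
  c0 <- max(1L, floor(min(a[2], b[2]) - pad)); c1 <- min(w, ceiling(max(a[2], b[2]) + pad))
  cov <- matrix(0, h, w)
  if (r0 > r1 || c0 > c1) return(cov)
  rows <- r0:r1; cols <- c0:c1
  ab <- b - a
  len2 <- sum(ab^2)
  pr <- matrix(rows - a[1], nrow = length(rows), ncol = length(cols))
  pc <- matrix(cols - a[2], nrow = length(rows), ncol = length(cols), byrow = TRUE)
  t <- if (len2 == 0) matrix(0, length(rows), length(cols))
       else pmin(1, pmax(0, (pr * ab[1] + pc * ab[2]) / len2))
  dr <- pr - t * ab[1]
  dc <- pc - t * ab[2]
  d <- sqrt(dr^2 + dc^2)
  cov[rows, cols] <- pmin(1, pmax(0, half + 0.5 - d))
  cov
}

## Euclidean length of a vertex matrix polyline (internal fast path).
segsum <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(rowSums(diff(v)^2)))
}

## 8-connected component labelling of a logical matrix (EBImage::bwlabel is
## 4-connected, which splits diagonal skeleton runs). Returns an integer
## matrix, 0 = background.
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  p <- which(mask, arr.ind = TRUE)
  n <- nrow(p)
  if (n == 0L) return(lab)
  key <- p[, 1] * 1e6 + p[, 2]
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  ef <- integer(0); et <- integer(0)
  for (k in seq_len(nrow(off))) {
    m <- match((p[, 1] + off[k, 1]) * 1e6 + (p[, 2] + off[k, 2]), key)
    hit <- which(!is.na(m))
    ef <- c(ef, hit); et <- c(et, m[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  lab[p] <- as.integer(comp)
  lab
}

## Bilinear interpolation of a matrix at fractional (row, col).
bilinear_at <- function(im, r, c) {
  r0 <- max(1L, min(nrow(im) - 1L, floor(r)))
  c0 <- max(1L, min(ncol(im) - 1L, floor(c)))
  fr <- r - r0; fc <- c - c0
  im[r0, c0] * (1 - fr) * (1 - fc) + im[r0 + 1L, c0] * fr * (1 - fc) +
    im[r0, c0 + 1L] * (1 - fr) * fc + im[r0 + 1L, c0 + 1L] * fr * fc
}

## Boxcar-smooth the interior of a pixel chain (endpoints fixed); removes
## the staircase wiggle of thinned skeletons before Euclidean summation.
smooth_chain <- function(v, window = 5L) {
  n <- nrow(v)
  if (n <= 3L) return(v)
  half <- window %/% 2L
  out <- v
  for (i in 2L:(n - 1L)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(v[lo:hi, , drop = FALSE])
  }
  out
}

## Douglas-Peucker polyline simplification on an n x 2 matrix.
simplify_polyline <- function(v, eps = 1.5) {
  n <- nrow(v)
  if (n <= 2L) return(v)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    a <- v[i, ]; b <- v[j, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    idx <- (i + 1L):(j - 1L)
    if (len == 0) {
      d <- sqrt(rowSums(sweep(v[idx, , drop = FALSE], 2, a)^2))
    } else {
      ap <- sweep(v[idx, , drop = FALSE], 2, a)
      d <- abs(ap[, 1] * ab[2] - ap[, 2] * ab[1]) / len
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- idx[k]
      keep[m] <- TRUE
      stack <- c(stack, list(c(i, m)), list(c(m, j)))
    }
  }
  v[keep, , drop = FALSE]
}
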