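## Shared fixture builders; everything is generated in code at test time.

small_scene_spec <- function(noiseSd = 0, ...) {
  neuronSceneSpec(imageHeightPx = 256L, imageWidthPx = 256L, nCells = 2L,
                  neuritesPerCell = 2L, neuriteLengthPxRange = c(25, 40),
                  branchProbability = 0, noiseSd = noiseSd, ...)
}

study_scene_spec <- function(...) {
  ## the five-cell, two-neurite scene used for tracing validation
  neuronSceneSpec(nCells = 5L, neuritesPerCell = 2L,
                  branchProbability = 0.3, noiseSd = 0, ...)
}

six_lane_amps <- function() {
  rbind(c(9000, 7000), c(4500, 7000), c(13500, 7000),
        c(7000, 7000), c(6000, 7000), c(11000, 7000))
}

## exhaustive enumeration of all root-to-leaf path lengths of a NeuriteTree;
## independent of the package's accumulation logic
enumerate_path_lengths <- function(tree) {
  e <- tree@edges
  n <- nrow(tree@nodes)
  if (n == 1L) return(0)
  children <- split(seq_len(nrow(e)), e$parent)
  walk <- function(node, acc) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) return(acc)
    unlist(lapply(kid_edges, function(ei)
      walk(e$child[ei], acc + e$weight[ei])))
  }
  walk(1L, 0)
}

## random rooted tree with <= max_nodes nodes and random edge weights
random_tree <- function(max_nodes = 12L) {
  n <- sample(2:max_nodes, 1L)
  coords <- matrix(runif(2 * n, 0, 100), n, 2)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1L, 1L), integer(1)))
  w <- runif(n - 1L, 0.5, 20)
  NeuriteTree(coords[1, ], coords,
              data.frame(parent = parent[-1L], child = 2:n, weight = w))
}
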