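#' Generate a nested measurement hierarchy with known grand mean
#'
#' Draws experiment-level offsets, picture-level offsets and within-picture
#' values from independent Gaussian components around the grand mean,
#' emulating a design of independent experiments run in duplicate with
#' several pictures per replicate and a bounded number of measurements per
#' picture. Ground truth records the grand mean and every component draw.
#'
#' @param spec a \linkS4class{HierarchySpec}.
#' @param seed integer seed.
#' @return List with \code{data} (data.frame \code{experiment},
#'   \code{replicate}, \code{picture_id}, \code{value}) and \code{truth}
#'   (list: \code{kind = "hierarchy"}, \code{grand_mean},
#'   \code{experiment_offsets}, per-picture offsets and counts).
#' @examples
#' hh <- generateMeasurementHierarchy(hierarchySpec(), seed = 3)
#' head(hh$data)
#' @export
generateMeasurementHierarchy <- function(spec, seed = 0L) {
  stopifnot(is(spec, "HierarchySpec"))
  validObject(spec)
  with_seed(seed, .generate_hierarchy(spec))
}

.generate_hierarchy <- function(spec) {
  rng <- spec@measurementsPerPictureRange
  expOff <- rnorm(spec@nExperiments, 0, spec@sdBetweenExperiments)
  rows <- vector("list", 0L)
  picOff <- list()
  for (e in seq_len(spec@nExperiments)) {
    for (r in seq_len(spec@replicatesPerExperiment)) {
      for (p in seq_len(spec@picturesPerReplicate)) {
        pid <- sprintf("E%d.R%d.P%d", e, r, p)
        off <- rnorm(1, 0, spec@sdBetweenPictures)
        m <- if (rng[1] == rng[2]) rng[1]
             else sample(seq.int(rng[1], rng[2]), 1L)
        vals <- spec@grandMean + expOff[e] + off +
                rnorm(m, 0, spec@sdWithinPicture)
        picOff[[pid]] <- list(offset = off, n = m)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = e, replicate = r, picture_id = pid, value = vals)
      }
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       truth = list(kind = "hierarchy", grand_mean = spec@grandMean,
                    experiment_offsets = expOff, pictures = picOff))
}

#' Generate an assay table with planted fold-change effects
#'
#' Emits rows \code{(condition, replicate, raw_value, protein_content)} such
#' that the expected protein-normalized value of each condition equals its
#' planted fold change times the control's. Raw values carry multiplicative
#' Gaussian noise of coefficient of variation \code{noise_cv}; protein
#' content varies uniformly around 1 so protein normalization is exercised.
#'
#' @param conditions character vector of condition labels.
#' @param fold_changes numeric vector aligned with \code{conditions}; the
#'   control condition's entry must be 1.
#' @param n_per_condition replicates per condition.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param control which condition is the control (default the first); its
#'   absence from \code{conditions} is an error.
#' @param base_level expected protein-normalized control value (assay units).
#' @return List with \code{data} (data.frame \code{condition},
#'   \code{replicate}, \code{raw_value}, \code{protein_content}) and
#'   \code{truth} (list: \code{kind = "assay"}, \code{control},
#'   \code{fold_changes} named by condition).
#' @examples
#' at <- generateAssayTable(c("ctrl", "treated"), c(1, 2), 4L, 0, seed = 1)
#' at$truth$fold_changes
#' @export
generateAssayTable <- function(conditions, fold_changes, n_per_condition,
                               noise_cv = 0.1, seed = 0L,
                               control = conditions[1], base_level = 50) {
  stopifnot(length(conditions) == length(fold_changes), n_per_condition >= 1L,
            noise_cv >= 0)
  if (!control %in% conditions)
    stop("control condition '", control, "' is not among the conditions")
  if (fold_changes[match(control, conditions)] != 1)
    stop("the control condition's fold change must be 1")
  with_seed(seed, {
    rows <- lapply(seq_along(conditions), function(i) {
      protein <- runif(n_per_condition, 0.8, 1.2)
      eps <- if (noise_cv > 0) rnorm(n_per_condition, 0, noise_cv) else 0
      data.frame(condition = conditions[i],
                 replicate = seq_len(n_per_condition),
                 raw_value = fold_changes[i] * base_level * protein * (1 + eps),
                 protein_content = protein)
    })
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    list(data = data,
         truth = list(kind = "assay", control = control,
                      fold_changes = stats::setNames(fold_changes, conditions)))
  })
}

#' Write a generator's ground truth as JSON
#'
#' Polyline vertices are written as arrays of 0-based \code{[row, col]} pairs.
#'
#' @param truth a \code{truth} list from any generator.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  t <- truth
  if (identical(t$kind, "neurites")) {
    t$neurites <- lapply(t$neurites, function(nt) {
      nt$paths <- lapply(nt$paths, function(v) unname(v - 1))
      nt$anchor <- unname(nt$anchor - 1)
      nt
    })
    t$soma_centres <- unname(t$soma_centres - 1)
  }
  jsonlite::write_json(t, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
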