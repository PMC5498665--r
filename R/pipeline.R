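## Workflow orchestration: the run* functions bind the stages into the three
## quantification workflows plus simulation, with file I/O, logging and a
## self-describing run manifest. A thin command-line wrapper over these
## functions lives in inst/scripts/neurimetry-cli.R.

.pkg_version <- function() as.character(utils::packageVersion("neurimetry"))

.log_stage <- function(stage, msg, verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Write a run manifest
#'
#' Records the tool version, the fully-materialized configuration (defaults
#' included, so runs are self-describing), md5 checksums of the inputs, a
#' timestamp and the per-stage log. Written at run end.
#'
#' @param outdir output directory.
#' @param config named list echoed verbatim.
#' @param inputs character vector of input file paths (checksummed).
#' @param stages character vector of stage log lines.
#' @return Path of the manifest, invisibly.
#' @export
writeRunManifest <- function(outdir, config, inputs = character(0),
                             stages = character(0)) {
  man <- list(tool = "neurimetry", version = .pkg_version(),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = config,
              input_checksums = if (length(inputs)) file_checksums(inputs)
                                else list(),
              stages = as.list(stages))
  path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build a generator spec from a JSON file
#'
#' Field names follow the snake_case external interface (e.g.
#' \code{image_height_px}); unknown fields are an error naming the field.
#'
#' @param kind one of "neurites", "blot", "fluorescence", "hierarchy".
#' @param path JSON spec file.
#' @return The corresponding spec object.
#' @export
specFromJson <- function(kind, path) {
  j <- jsonlite::fromJSON(path)
  maps <- list(
    neurites = c(image_height_px = "imageHeightPx", image_width_px = "imageWidthPx",
      n_cells = "nCells", soma_radius_px = "somaRadiusPx",
      neurites_per_cell = "neuritesPerCell",
      neurite_length_px_range = "neuriteLengthPxRange",
      branch_probability = "branchProbability", neurite_width_px = "neuriteWidthPx",
      foreground_intensity = "foregroundIntensity",
      background_intensity = "backgroundIntensity", noise_sd = "noiseSd",
      um_per_px = "umPerPx"),
    blot = c(lanes = "lanes", band_sigma_px = "bandSigmaPx",
      lane_pitch_px = "lanePitchPx", background_level = "backgroundLevel",
      background_gradient = "backgroundGradient", noise_sd = "noiseSd"),
    fluorescence = c(n_nuclei = "nNuclei", nucleus_radius_px = "nucleusRadiusPx",
      marker_fraction_positive = "markerFractionPositive",
      marker_amplitude = "markerAmplitude", nucleus_amplitude = "nucleusAmplitude",
      threshold_truth = "thresholdTruth", noise_sd = "noiseSd",
      image_shape = "imageShape"),
    hierarchy = c(n_experiments = "nExperiments",
      replicates_per_experiment = "replicatesPerExperiment",
      pictures_per_replicate = "picturesPerReplicate",
      measurements_per_picture_range = "measurementsPerPictureRange",
      grand_mean = "grandMean", sd_between_experiments = "sdBetweenExperiments",
      sd_between_pictures = "sdBetweenPictures",
      sd_within_picture = "sdWithinPicture"))
  kind <- match.arg(kind, names(maps))
  map <- maps[[kind]]
  unknown <- setdiff(names(j), names(map))
  if (length(unknown))
    stop("unknown spec field(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  args <- stats::setNames(j, map[names(j)])
  ctor <- switch(kind, neurites = neuronSceneSpec, blot = blotSpec,
                 fluorescence = fluorPairSpec, hierarchy = hierarchySpec)
  do.call(ctor, args)
}

#' Simulate a dataset with ground truth
#'
#' Generates images/tables plus a machine-readable ground-truth JSON under
#' \code{outdir}. For neurite scenes it also writes the soma mask, the truth
#' polylines as an annotation file, and for blots a default ROI manifest.
#'
#' @param kind "neurites", "blot", "fluorescence", "hierarchy" or "assay".
#' @param spec spec object of the matching class (or, for "assay", a list
#'   with \code{conditions}, \code{fold_changes}, \code{n_per_condition},
#'   \code{noise_cv}); a character path is parsed with
#'   \code{\link{specFromJson}}.
#' @param seed integer seed.
#' @param outdir output directory (created).
#' @param picture_id picture identifier recorded in neurite annotation
#'   output; defaults to the output directory's basename.
#' @param verbose log stage lines.
#' @return Invisibly, the generated object (as from the generator).
#' @export
runSimulate <- function(kind, spec, seed = 0L, outdir, picture_id = NULL,
                        verbose = FALSE) {
  kind <- match.arg(kind, c("neurites", "blot", "fluorescence", "hierarchy",
                            "assay"))
  if (is.character(spec) && kind != "assay") spec <- specFromJson(kind, spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  res <- switch(kind,
    neurites = {
      sc <- generateNeuronScene(spec, seed)
      writeMicrograph(sc$image, file.path(outdir, "scene.tif"))
      png::writePNG(sc$somaMask * 1, file.path(outdir, "soma_mask.png"))
      writeGroundTruth(sc$truth, file.path(outdir, "ground_truth.json"))
      longest <- lapply(sc$truth$neurites, function(nt)
        Polyline(nt$paths[[which.max(vapply(nt$paths, segsum, numeric(1)))]]))
      if (is.null(picture_id)) picture_id <- basename(normalizePath(outdir))
      writeAnnotations(longest, picture_id, spec@umPerPx,
                       file.path(outdir, "annotations.json"))
      stages <- c(stages, sprintf("simulate: %d neurites drawn",
                                  length(sc$truth$neurites)))
      sc
    },
    blot = {
      b <- generateBlotImage(spec, seed)
      writeMicrograph(b$image, file.path(outdir, "blot.tif"))
      writeGroundTruth(b$truth, file.path(outdir, "ground_truth.json"))
      rois <- defaultBlotRois(b$truth)
      bands <- unlist(lapply(rois, function(l) {
        as_entry <- function(label, band, bg, isLoad) list(
          label = label, lane = paste0("lane", l$lane),
          is_loading_control = isLoad,
          roi = c(band@top - 1L, band@left - 1L, band@height, band@width),
          background_roi = c(bg@top - 1L, bg@left - 1L, bg@height, bg@width))
        list(as_entry("target", l$target, l$target_bg, FALSE),
             as_entry("loading", l$loading, l$loading_bg, TRUE))
      }), recursive = FALSE)
      jsonlite::write_json(list(image = "blot.tif", bands = bands),
                           file.path(outdir, "roi_manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stages <- c(stages, sprintf("simulate: %d lanes", length(b$truth$lanes)))
      b
    },
    fluorescence = {
      fp <- generateFluorescencePair(spec, seed)
      writeMicrograph(fp$marker, file.path(outdir, "marker.tif"))
      writeMicrograph(fp$nucleus, file.path(outdir, "nucleus.tif"))
      writeGroundTruth(fp$truth, file.path(outdir, "ground_truth.json"))
      stages <- c(stages, "simulate: fluorescence pair")
      fp
    },
    hierarchy = {
      hh <- generateMeasurementHierarchy(spec, seed)
      utils::write.csv(hh$data, file.path(outdir, "hierarchy.csv"),
                       row.names = FALSE)
      writeGroundTruth(hh$truth, file.path(outdir, "ground_truth.json"))
      stages <- c(stages, sprintf("simulate: %d measurements", nrow(hh$data)))
      hh
    },
    assay = {
      at <- do.call(generateAssayTable, c(spec, list(seed = seed)))
      utils::write.csv(at$data, file.path(outdir, "assay.csv"),
                       row.names = FALSE)
      writeGroundTruth(at$truth, file.path(outdir, "ground_truth.json"))
      stages <- c(stages, sprintf("simulate: %d rows", nrow(at$data)))
      at
    })
  for (s in stages) .log_stage("simulate", s, verbose)
  writeRunManifest(outdir, list(command = "simulate", kind = kind,
                                seed = seed), stages = stages)
  invisible(res)
}

#' Derive a soma mask from a phase-contrast micrograph
#'
#' Otsu-binarizes the raw image and applies a disc opening so that thin
#' structures (neurites) vanish while compact bright somata survive;
#' components below \code{min_area_px} are dropped.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param brush_px odd diameter of the opening brush (default 9).
#' @param min_area_px minimum component area to keep (default 30).
#' @return Logical matrix marking somata.
#' @export
somaMaskFromImage <- function(image, brush_px = 9L, min_area_px = 30) {
  stopifnot(is(image, "Micrograph"))
  thr <- otsu_threshold(as.vector(image@pixels))
  bin <- image@pixels > thr
  op <- EBImage::opening(bin, EBImage::makeBrush(as.integer(brush_px), "disc"))
  lab <- label8(matrix(as.logical(op), nrow(op), ncol(op)))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    op[matrix(lab %in% which(areas < min_area_px), nrow(op), ncol(op))] <- FALSE
  }
  matrix(as.logical(op), nrow(op), ncol(op))
}

#' Run the neurite-length workflow
#'
#' Annotation mode measures operator-supplied polylines (the exact reference
#' path); trace mode runs enhancement and automated tracing on images. Both
#' end in the hierarchical pooling chain: picture means weighted by
#' measurement count within replicates, inverse-variance pooling of
#' replicates and of experiments.
#'
#' @param inputs in annotation mode, character paths of annotation JSON
#'   files; in trace mode, character paths of grayscale images.
#' @param mode "annotation" or "trace".
#' @param experiment,replicate integer vectors aligned with \code{inputs}
#'   (default all 1), placing every picture in the design.
#' @param um_per_px calibration for trace mode (annotation files carry their
#'   own); required there.
#' @param params filter parameters for trace mode.
#' @param min_length_px tracing length cut-off.
#' @param outdir optional output directory for CSV/JSON results and overlays.
#' @param verbose log stage lines.
#' @return List with \code{measurements} (data.frame picture_id,
#'   neurite_index, length_um), \code{pictures} (per-picture n and mean) and
#'   \code{pooled} (\linkS4class{PooledEstimate}).
#' @export
runNeurites <- function(inputs, mode = c("annotation", "trace"),
                        experiment = rep(1L, length(inputs)),
                        replicate = rep(1L, length(inputs)),
                        um_per_px = NULL, params = filterParams(),
                        min_length_px = 10, outdir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(inputs) == 0L) stop("no input pictures")
  stages <- character(0)
  rows <- list(); hier <- list()
  for (i in seq_along(inputs)) {
    if (mode == "annotation") {
      ann <- readAnnotations(inputs[i])
      traces <- ann$polylines
      cal <- ann$um_per_px
      pid <- ann$picture_id
    } else {
      if (is.null(um_per_px)) stop("missing calibration for picture ", inputs[i])
      img <- readMicrograph(inputs[i])
      edges <- enhanceNeurites(img, params)
      soma <- somaMaskFromImage(img)
      traces <- traceNeurites(edges, soma, min_length_px)
      cal <- um_per_px
      pid <- tools::file_path_sans_ext(basename(inputs[i]))
      if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeOverlay(overlayEdges(img, edges),
                     file.path(outdir, paste0(pid, "_overlay.png")))
      }
    }
    if (length(traces) == 0L) {
      stages <- c(stages, sprintf("neurites: picture %s excluded (no traces)", pid))
      next
    }
    pm <- measurePicture(traces, cal, pid)
    rows[[length(rows) + 1L]] <- data.frame(
      picture_id = pid, neurite_index = seq_along(pm$lengths_um),
      length_um = pm$lengths_um)
    hier[[length(hier) + 1L]] <- data.frame(
      experiment = experiment[i], replicate = replicate[i],
      picture_id = pid, value = pm$lengths_um)
    stages <- c(stages, sprintf("neurites: picture %s, n = %d", pid, pm$n))
  }
  if (!length(rows)) stop("all pictures excluded: nothing to pool")
  measurements <- do.call(rbind, rows)
  hierData <- do.call(rbind, hier)
  pooled <- hierarchicalNeuriteMean(hierData)
  pictures <- do.call(rbind, lapply(split(hierData, hierData$picture_id),
    function(d) data.frame(picture_id = d$picture_id[1], n = nrow(d),
                           mean_length_um = mean(d$value))))
  rownames(pictures) <- NULL
  for (s in stages) .log_stage("neurites", s, verbose)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(outdir, "measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mode = mode, mean_um = pooled@mean,
                              se_um = sqrt(pooled@varianceOfMean),
                              n_levels = pooled@nLevels,
                              weights = pooled@weights),
                         file.path(outdir, "pooled_estimate.json"),
                         auto_unbox = TRUE, digits = NA)
    writeRunManifest(outdir, list(command = "neurites", mode = mode,
                                  min_length_px = min_length_px),
                     inputs = inputs, stages = stages)
  }
  list(measurements = measurements, pictures = pictures, pooled = pooled)
}

#' Run the densitometry workflow on one blot image
#'
#' Computes every band's IDV (after validating that all band ROIs share one
#' dimension), normalizes each lane's target band to its loading control,
#' and expresses lane ratios as fold changes versus the reference lane.
#'
#' @param image a \linkS4class{Micrograph} or image path.
#' @param manifest ROI manifest list (as from \code{\link{readRoiManifest}})
#'   or path to a manifest JSON.
#' @param reference reference lane name (fold change 1).
#' @param invert film polarity inversion (default TRUE).
#' @param outdir optional output directory.
#' @param verbose log stage lines.
#' @return data.frame \code{lane}, \code{label}, \code{idv}, \code{ratio},
#'   \code{fold_change}.
#' @export
runDensitometry <- function(image, manifest, reference, invert = TRUE,
                            outdir = NULL, verbose = FALSE) {
  manifestPath <- NULL
  if (is.character(manifest)) {
    manifestPath <- manifest
    manifest <- readRoiManifest(manifest)
  }
  if (is.character(image)) image <- readMicrograph(image)
  bands <- manifest$bands
  enforceUniformRoi(lapply(bands, `[[`, "roi"))
  quants <- lapply(bands, function(b)
    integratedDensity(image, b$roi, b$background_roi, invert = invert))
  lanes <- unique(vapply(bands, `[[`, character(1), "lane"))
  rows <- list(); ratios <- c()
  for (ln in lanes) {
    inLane <- which(vapply(bands, function(b) b$lane == ln, logical(1)))
    isLoad <- vapply(bands[inLane], `[[`, logical(1), "is_loading_control")
    if (!any(isLoad))
      stop("lane '", ln, "' has no loading-control band")
    loadQ <- quants[[inLane[which(isLoad)[1]]]]
    for (ix in inLane[!isLoad]) {
      r <- normalizeBand(quants[[ix]], loadQ)
      ratios[ln] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        lane = ln, label = bands[[ix]]$label, idv = quants[[ix]]@idv,
        loading_idv = loadQ@idv, ratio = r)
    }
  }
  if (!reference %in% names(ratios))
    stop("reference lane '", reference, "' not found")
  fc <- foldChange(ratios, reference)
  res <- do.call(rbind, rows)
  res$fold_change <- unname(fc[res$lane])
  .log_stage("densitometry", sprintf("%d lanes, reference %s", length(lanes),
                                     reference), verbose)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(outdir, "lane_table.csv"),
                     row.names = FALSE)
    writeRunManifest(outdir, list(command = "densitometry",
                                  reference = reference, invert = invert),
                     inputs = if (is.null(manifestPath)) character(0)
                              else manifestPath,
                     stages = sprintf("densitometry: %d bands", length(bands)))
  }
  res
}

#' Run the relative-fluorescence-intensity workflow
#'
#' Computes the per-picture RFI for every marker/nucleus pair, pools each
#' condition (inverse-variance across experiments when an experiment column
#' is present, otherwise a plain per-condition summary), and when two or
#' more conditions have two or more pictures each, runs one-way ANOVA with
#' Tukey post-hoc comparisons on the per-picture RFIs. Pictures with zero
#' nucleus signal are excluded with a logged reason; the run continues.
#'
#' @param pairs data.frame with columns \code{picture_id},
#'   \code{marker_path}, \code{nucleus_path}, \code{condition} (optional
#'   \code{experiment}), or the path of such a CSV manifest.
#' @param policy marker threshold policy (\code{\link{thresholdPolicy}}).
#' @param nucleus_policy nucleus threshold policy; defaults to \code{policy}.
#' @param alpha significance level for the comparisons.
#' @param outdir optional output directory.
#' @param verbose log stage lines.
#' @return List with \code{per_picture} (data.frame), \code{excluded}
#'   (character picture ids), \code{condition_summaries}, \code{anova}
#'   (\linkS4class{AnovaResult} or NULL) and \code{tukey} (data.frame or
#'   NULL).
#' @export
runRfi <- function(pairs, policy, nucleus_policy = policy, alpha = 0.05,
                   outdir = NULL, verbose = FALSE) {
  manifestPath <- NULL
  if (is.character(pairs)) {
    manifestPath <- pairs
    pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE)
  }
  req <- c("picture_id", "marker_path", "nucleus_path", "condition")
  if (!all(req %in% names(pairs)))
    stop("pair manifest needs columns ", paste(req, collapse = ", "))
  rows <- list(); excluded <- character(0); stages <- character(0)
  for (i in seq_len(nrow(pairs))) {
    marker <- readMicrograph(pairs$marker_path[i], channel = "marker")
    nucleus <- readMicrograph(pairs$nucleus_path[i], channel = "nucleus")
    res <- tryCatch(rfi(marker, nucleus, policy, nucleus_policy),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, pairs$picture_id[i])
      stages <- c(stages, sprintf("rfi: picture %s excluded (%s)",
                                  pairs$picture_id[i], conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      picture_id = pairs$picture_id[i], condition = pairs$condition[i],
      experiment = if ("experiment" %in% names(pairs)) pairs$experiment[i]
                   else 1L,
      marker_sum = res@markerSum, nucleus_sum = res@nucleusSum,
      rfi = res@rfi)
    stages <- c(stages, sprintf("rfi: picture %s, rfi %.4g",
                                pairs$picture_id[i], res@rfi))
  }
  if (!length(rows)) stop("all pictures excluded: no RFI computed")
  per <- do.call(rbind, rows)

  condSummaries <- lapply(split(per, per$condition), function(d) {
    byExp <- split(d$rfi, d$experiment)
    if (length(byExp) >= 2L && all(lengths(byExp) >= 1L)) {
      s <- lapply(names(byExp), function(e) summarizeLevel(byExp[[e]], e))
      inverseVariancePool(s)
    } else summarizeLevel(d$rfi, d$condition[1])
  })

  groups <- split(per$rfi, per$condition)
  anova <- NULL; tukey <- NULL
  if (length(groups) >= 2L && all(lengths(groups) >= 2L)) {
    anova <- tryCatch(oneWayAnova(groups), error = function(e) NULL)
    tukey <- tryCatch(tukeyHsd(groups, alpha), error = function(e) NULL)
  }
  for (s in stages) .log_stage("rfi", s, verbose)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per, file.path(outdir, "rfi_per_picture.csv"),
                     row.names = FALSE)
    if (!is.null(tukey))
      utils::write.csv(tukey, file.path(outdir, "tukey_comparisons.csv"),
                       row.names = FALSE)
    writeRunManifest(outdir, list(command = "rfi", alpha = alpha,
                                  policy = policy),
                     inputs = if (is.null(manifestPath)) character(0)
                              else manifestPath, stages = stages)
  }
  list(per_picture = per, excluded = excluded,
       condition_summaries = condSummaries, anova = anova, tukey = tukey)
}
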