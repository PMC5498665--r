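#' Summarize one aggregation level
#'
#' Sample mean, unbiased sample variance and count of a vector of
#' measurements. With a single value the variance is 0 and flagged
#' degenerate.
#'
#' @param values non-empty numeric vector.
#' @param label level identifier.
#' @return A \linkS4class{LevelSummary}.
#' @examples
#' summarizeLevel(c(1, 2, 3), "p1")  # mean 2, variance 1, n 3
#' @export
summarizeLevel <- function(values, label = "") {
  if (length(values) == 0L) stop("cannot summarize an empty level")
  stopifnot(all(is.finite(values)))
  n <- length(values)
  v <- if (n >= 2L) stats::var(values) else 0
  LevelSummary(mean(values), v, n, label, degenerate = (n < 2L || v == 0))
}

#' Pool level summaries weighted by measurement count
#'
#' The mean of each picture is weighted by the number of measurements taken:
#' \code{mean = sum(n_i m_i) / sum(n_i)}. The variance carried upward (needed
#' as the next pooling level's weight) is the count-weighted sample variance
#' of the member means about the pooled mean, with the frequency-weights
#' unbiased correction \code{k/(k-1)}; it is 0 and degenerate for a single
#' member.
#'
#' @param summaries non-empty list of \linkS4class{LevelSummary}.
#' @param label label of the pooled level.
#' @return A \linkS4class{LevelSummary} with \code{n = sum(n_i)}.
#' @export
weightedMeanByCount <- function(summaries, label = "") {
  if (length(summaries) == 0L) stop("no summaries to pool")
  m <- vapply(summaries, function(s) s@mean, numeric(1))
  n <- vapply(summaries, function(s) s@n, integer(1))
  k <- length(m)
  N <- sum(n)
  mu <- sum(n * m) / N
  v <- if (k >= 2L) (k / (k - 1)) * sum(n * (m - mu)^2) / N else 0
  LevelSummary(mu, v, N, label, degenerate = (k < 2L || v == 0))
}

#' Inverse-variance weighted pooling
#'
#' Pools member estimates with weights proportional to the reciprocal of
#' their variances: \code{w_i = (1/v_i) / sum(1/v_j)}, \code{mean = sum(w_i
#' m_i)}, \code{variance_of_mean = 1 / sum(1/v_i)} — the minimum-variance
#' combination for independent unbiased members.
#'
#' Degenerate members (variance 0, from n = 1 or identical values) would
#' otherwise receive infinite weight; the fallback substitutes the smallest
#' positive member variance for them, and when no member has positive
#' variance the pool falls back to count weighting with a variance of 0.
#'
#' @param summaries non-empty list of \linkS4class{LevelSummary}.
#' @return A \linkS4class{PooledEstimate}.
#' @examples
#' s <- list(summarizeLevel(c(1, 3), "a"), summarizeLevel(c(4, 8), "b"))
#' poolMean(inverseVariancePool(s))
#' @export
inverseVariancePool <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries to pool")
  m <- vapply(summaries, function(s) s@mean, numeric(1))
  v <- vapply(summaries, function(s) s@variance, numeric(1))
  n <- vapply(summaries, function(s) s@n, integer(1))
  if (any(v < 0)) stop("negative variance in pool input")
  k <- length(m)
  if (any(v == 0)) {
    pos <- v[v > 0]
    if (length(pos)) {
      v[v == 0] <- min(pos)
    } else {
      w <- n / sum(n)
      return(new("PooledEstimate", mean = sum(w * m), varianceOfMean = 0,
                 nLevels = as.integer(k), weights = w))
    }
  }
  w <- (1 / v) / sum(1 / v)
  new("PooledEstimate", mean = sum(w * m),
      varianceOfMean = 1 / sum(1 / v), nLevels = as.integer(k), weights = w)
}

#' Hierarchical weighted mean of nested neurite measurements
#'
#' Composes the full aggregation chain of the neurite-length design, in fixed
#' order: per-picture summaries, then picture means within each replicate
#' pooled with weights equal to the number of measurements taken, then
#' replicate means within each experiment pooled by inverse variance, and
#' finally the experiment means pooled by inverse variance into the overall
#' estimate.
#'
#' @param data data.frame with columns \code{experiment}, \code{replicate},
#'   \code{picture_id}, \code{value}; every picture must have at least one
#'   value.
#' @return A \linkS4class{PooledEstimate} for the overall mean.
#' @export
hierarchicalNeuriteMean <- function(data) {
  req <- c("experiment", "replicate", "picture_id", "value")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "))
  if (nrow(data) == 0L) stop("no measurements")
  expSummaries <- lapply(split(data, data$experiment), function(de) {
    repSummaries <- lapply(split(de, de$replicate), function(dr) {
      picSummaries <- lapply(split(dr, dr$picture_id), function(dp)
        summarizeLevel(dp$value, dp$picture_id[1]))
      weightedMeanByCount(unname(picSummaries),
                          sprintf("E%s.R%s", de$experiment[1], dr$replicate[1]))
    })
    pe <- inverseVariancePool(unname(repSummaries))
    LevelSummary(pe@mean, pe@varianceOfMean, sum(vapply(repSummaries,
                 function(s) s@n, integer(1))),
                 sprintf("E%s", de$experiment[1]),
                 degenerate = (pe@varianceOfMean == 0))
  })
  inverseVariancePool(unname(expSummaries))
}

#' Normalize an assay reading to protein content and to its control
#'
#' Assay readings (e.g. acetylcholine concentration, acetylcholinesterase
#' activity, viability absorbance) are normalized to the sample's protein
#' content when available and then to the respective control:
#' \code{(raw / protein) / control_value}.
#'
#' @param raw raw assay reading.
#' @param protein_content optional positive protein amount; omit (NULL) for
#'   assays reported per well.
#' @param control_value positive control-level value on the same
#'   (protein-normalized) scale.
#' @return Normalized value; 1 for a control sample against itself.
#' @examples
#' normalizeAssay(10, 2, 5)  # 1
#' @export
normalizeAssay <- function(raw, protein_content = NULL, control_value) {
  if (!is.null(protein_content)) {
    if (!is.finite(protein_content) || protein_content <= 0)
      stop("protein_content must be positive")
    raw <- raw / protein_content
  }
  if (!is.finite(control_value) || control_value <= 0)
    stop("control_value must be positive")
  raw / control_value
}

#' Normalize a generated assay table and recover per-condition fold changes
#'
#' Protein-normalizes every row, anchors on the mean protein-normalized
#' control value, and returns per-row normalized values plus per-condition
#' mean fold changes.
#'
#' @param data data.frame with columns \code{condition}, \code{raw_value},
#'   \code{protein_content}.
#' @param control control condition label.
#' @return List with \code{per_row} (input plus \code{normalized}) and
#'   \code{fold_changes} (named per-condition means).
#' @export
normalizeAssayTable <- function(data, control) {
  req <- c("condition", "raw_value", "protein_content")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "))
  if (!control %in% data$condition)
    stop("control condition '", control, "' absent from the table")
  perProtein <- data$raw_value / data$protein_content
  ctrl <- mean(perProtein[data$condition == control])
  normalized <- vapply(perProtein, normalizeAssay, numeric(1),
                       protein_content = NULL, control_value = ctrl)
  out <- data
  out$normalized <- normalized
  fc <- tapply(normalized, data$condition, mean)
  list(per_row = out, fold_changes = fc[unique(data$condition)])
}
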