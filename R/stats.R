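#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA at 95% confidence: the F statistic
#' from the between/within sum-of-squares decomposition, with the p value
#' from the upper tail of the F distribution (computed through
#' \code{stats::oneway.test} with equal variances assumed).
#'
#' @param groups named list of numeric vectors, one per condition; at least
#'   two groups of at least two values each, with positive pooled
#'   within-group variance.
#' @return An \linkS4class{AnovaResult}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
oneWayAnova <- function(groups) {
  .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  new("AnovaResult", fStatistic = max(0, unname(ft$statistic)),
      dfBetween = as.integer(unname(ft$parameter[1])),
      dfWithin = as.integer(unname(ft$parameter[2])),
      pValue = unname(ft$p.value))
}

.check_groups <- function(groups, alpha = NULL) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least two values")
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw <= 0)
    stop("degenerate within-group variance: ANOVA undefined")
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1))
    stop("alpha must be in (0, 1)")
  invisible(TRUE)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA using the studentized
#' range: \code{q = |m_i - m_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))} (the
#' Tukey-Kramer form, exact for balanced designs and conservative for
#' unequal group sizes), compared against the studentized-range critical
#' value at \code{(k, df_within)} and the chosen alpha. The family of
#' comparisons is controlled per response variable; no cross-variable
#' correction is applied.
#'
#' @param groups named list of numeric vectors (ANOVA preconditions apply).
#' @param alpha family-wise significance level in (0, 1), default 0.05.
#' @return data.frame with columns \code{group_a}, \code{group_b},
#'   \code{mean_difference} (b minus a), \code{q_statistic}, \code{p_value}
#'   and \code{significant}.
#' @examples
#' tukeyHsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12)))
#' @export
tukeyHsd <- function(groups, alpha = 0.05) {
  .check_groups(groups, alpha)
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  dfW <- sum(n) - k
  msw <- ssw / dfW
  qcrit <- stats::qtukey(1 - alpha, k, dfW)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(m[i] - m[j]) / se
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               mean_difference = m[j] - m[i], q_statistic = q,
               p_value = 1 - stats::ptukey(q, k, dfW),
               significant = q > qcrit)
  })
  res <- do.call(rbind, out)
  attr(res, "q_critical") <- qcrit
  attr(res, "alpha") <- alpha
  res
}

#' Critical value of the studentized range
#'
#' Convenience wrapper for the studentized-range quantile used by the Tukey
#' test.
#'
#' @param k number of groups.
#' @param df within-group degrees of freedom.
#' @param alpha significance level.
#' @return Numeric critical value.
#' @export
tukeyCriticalValue <- function(k, df, alpha = 0.05) {
  stats::qtukey(1 - alpha, k, df)
}

#' Determination coefficient between paired measurements
#'
#' R-squared of the least-squares line of y on x: \code{1 - SS_res /
#' SS_tot}. Used, for instance, to relate indirect cell counts from nuclear
#' staining to a metabolic viability readout.
#'
#' @param x,y numeric vectors of equal length >= 3; y must not be constant.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' determinationCoefficient(1:5, 2 * (1:5) + 1)  # R^2 = 1
#' @export
determinationCoefficient <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(y) == 0) stop("constant y: determination coefficient undefined")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  new("CorrelationResult", rSquared = min(1, max(0, r2)),
      nPairs = as.integer(length(x)))
}
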