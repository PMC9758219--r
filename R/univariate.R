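# Moderated two-group t-test with empirical-Bayes variance shrinkage,
# Benjamini-Hochberg FDR q-values, log2 fold changes, and the q <= 0.05
# prioritization filter. The two-group contrast (umami vs non-umami) is
# the only design supported; the per-feature sample variance is shrunk
# toward a prior estimated across all features by moment matching of the
# scaled-F distribution of log variances.

#' Per-feature log2 fold change
#'
#' \code{log2(mean_pos / mean_neg)} per feature, with a small epsilon
#' added to both class means when either is at or below zero (values are
#' expected on the normalized [0,1] scale).
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (1 = umami).
#' @param eps epsilon guarding zero means, default 1e-8.
#' @return named numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(X, y, eps = 1e-8) {
  y <- as.integer(y)
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be present")
  mPos <- colMeans(X[y == 1L, , drop = FALSE])
  mNeg <- colMeans(X[y == 0L, , drop = FALSE])
  shift <- ifelse(mPos <= 0 | mNeg <= 0, eps, 0)
  # NaN for genuinely negative means: the ratio has no log there and the
  # statistic is only contracted for the normalized non-negative scale
  suppressWarnings(log2((mPos + shift) / (mNeg + shift)))
}

# Newton inversion of the trigamma function (decreasing, convex on
# (0, Inf)); used by the moment-matching prior fit.
.trigammaInverse <- function(x) {
  vapply(x, function(z) {
    if (!is.finite(z)) return(0)
    if (z <= 0) return(Inf)
    if (z > 1e7) return(1 / sqrt(z))
    if (z < 1e-6) return(1 / z)
    y <- 0.5 + 1 / z
    for (it in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / z) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates prior degrees of freedom \code{d0} and prior variance
#' \code{s0sq} from the per-feature sample variances by moment matching
#' the scaled-F distribution of log variances (digamma/trigamma
#' matching). When the observed dispersion of log variances does not
#' exceed its theoretical minimum, \code{d0} is reported unbounded
#' (\code{Inf}) and \code{s0sq} is the common variance level.
#'
#' @param s2 per-feature sample variances (positive, possibly with zeros).
#' @param dg residual degrees of freedom of each variance (scalar).
#' @return An \linkS4class{EBayesPrior}.
#' @export
fitEbayesPrior <- function(s2, dg) {
  s2 <- as.numeric(s2)
  if (all(s2 <= 0)) stop("all variances are zero")
  ok <- s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2L) stop("need at least 2 features with positive variance")
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e)
  excess <- evar - trigamma(dg / 2)
  if (!is.finite(excess) || excess <= 0) {
    # zero excess dispersion: variances share one level; its moment
    # estimate is the arithmetic mean (E[s^2] = s0^2 under d0 = Inf)
    return(new("EBayesPrior", d0 = Inf, s0sq = mean(s2)))
  }
  d0 <- 2 * .trigammaInverse(excess)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  new("EBayesPrior", d0 = d0, s0sq = s0sq)
}

#' Moderated two-group t-test
#'
#' Pooled two-sample t statistics with the per-feature variance replaced
#' by the shrunken value
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and two-sided p-values from the t distribution on \code{d0 + dg}
#' degrees of freedom. In the \code{d0 = 0} limit this is the ordinary
#' pooled t-test; in the unbounded-\code{d0} limit every feature is tested
#' against the common prior variance.
#'
#' @param X numeric matrix, samples x features (no missing values).
#' @param y binary labels (1 = umami).
#' @param prior an \linkS4class{EBayesPrior}, or NULL to fit it from the
#'   data.
#' @param eps epsilon passed to \code{\link{log2FoldChange}}.
#' @return data.frame with one row per feature: \code{feature},
#'   \code{mean_pos}, \code{mean_neg}, \code{log2FC}, \code{s2},
#'   \code{df}, \code{t}, \code{p}.
#' @export
moderatedTTest <- function(X, y, prior = NULL, eps = 1e-8) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 samples")
  X1 <- X[y == 1L, , drop = FALSE]
  X0 <- X[y == 0L, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- apply(X1, 2, stats::var)
  v0 <- apply(X0, 2, stats::var)
  dg <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / dg
  if (is.null(prior)) prior <- fitEbayesPrior(s2, dg)
  d0 <- prior@d0; s0 <- prior@s0sq
  s2tilde <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + dg * s2) / (d0 + dg)
  se <- sqrt(s2tilde * (1 / n1 + 1 / n0))
  tmod <- (m1 - m0) / se
  # total df capped at the pooled residual df across features: with an
  # unbounded prior the evidence about the common variance is still finite
  dfTotal <- min(d0 + dg, length(s2) * dg)
  p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
  data.frame(feature = colnames(X), mean_pos = m1, mean_neg = m0,
             log2FC = log2FoldChange(X, y, eps = eps), s2 = s2, df = dg,
             t = tmod, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to q-values by the BH step-up procedure
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, clipped at 1 and returned
#' in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Feature statistics table for the two-group contrast
#'
#' Convenience wrapper running \code{\link{moderatedTTest}},
#' \code{\link{bhAdjust}} and the significance call at \code{qThreshold}.
#'
#' @inheritParams moderatedTTest
#' @param qThreshold q-value cutoff, default 0.05.
#' @return The moderated-t data.frame extended with \code{q} and
#'   \code{significant}.
#' @export
featureStats <- function(X, y, prior = NULL, qThreshold = 0.05,
                         eps = 1e-8) {
  st <- moderatedTTest(X, y, prior = prior, eps = eps)
  st$q <- bhAdjust(st$p)
  st$significant <- st$q <= qThreshold
  st
}

#' Prioritized feature list
#'
#' Features with \code{q <= qThreshold}, ordered by ascending q, then
#' descending absolute log2 fold change, then feature name (deterministic
#' tie-break).
#'
#' @param stats a data.frame from \code{\link{featureStats}}.
#' @param qThreshold q-value cutoff, default 0.05.
#' @return character vector of feature names.
#' @export
prioritizeFeatures <- function(stats, qThreshold = 0.05) {
  keep <- stats[stats$q <= qThreshold, , drop = FALSE]
  if (!nrow(keep)) return(character(0))
  ord <- order(keep$q, -abs(keep$log2FC), keep$feature)
  keep$feature[ord]
}

#' Export the volcano-plot table
#'
#' Writes the per-feature statistics behind a volcano representation
#' (feature, log2FC, p, q, significant) to CSV.
#'
#' @param stats a data.frame from \code{\link{featureStats}}.
#' @param path output file.
#' @export
writeVolcanoCsv <- function(stats, path) {
  utils::write.csv(stats[, c("feature", "log2FC", "p", "q",
                             "significant")], path, row.names = FALSE)
  invisible(path)
}
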