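# The four ranking/selection methods the evolutionary optimizer draws on:
# Wilcoxon rank-sum, kBest (one-way F), MRMR and JMIM. Ranking methods
# return a full permutation of the features; the greedy mutual-information
# methods return a best-first prefix. Ties break on the lowest feature
# index so every method is exactly reproducible.

.rankedFrame <- function(method, features, scores, order) {
  data.frame(method = method, rank = seq_along(order),
             feature = features[order], score = scores[order],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum feature ranking
#'
#' Per-feature two-sided rank-sum test between the classes: exact when the
#' combined sample size is at most 12 and there are no ties, the normal
#' approximation with tie correction otherwise. Constant features get
#' p = 1 by convention. Features are ranked by ascending p-value.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels.
#' @return data.frame with columns \code{method}, \code{rank},
#'   \code{feature}, \code{score} (the p-value), best first.
#' @export
wilcoxonRank <- function(X, y) {
  y <- as.integer(y)
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be present")
  n <- length(y)
  p <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) == 1L) return(1)
    exact <- n <= 12 && !anyDuplicated(x)
    suppressWarnings(stats::wilcox.test(
      x[y == 1L], x[y == 0L], exact = exact,
      correct = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  ord <- order(p, seq_along(p))
  .rankedFrame("wilcoxon", colnames(X), p, ord)
}

#' kBest univariate F-score ranking
#'
#' Per-feature one-way ANOVA F statistic between the two classes, ranked
#' descending. A feature with zero between-class difference and zero
#' within-class variance scores 0.
#'
#' @inheritParams wilcoxonRank
#' @return data.frame as in \code{\link{wilcoxonRank}} with the F score.
#' @export
kbestRank <- function(X, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  n <- n1 + n0
  X1 <- X[y == 1L, , drop = FALSE]
  X0 <- X[y == 0L, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums(sweep(X1, 2, m1)^2) + colSums(sweep(X0, 2, m0)^2)
  f <- ifelse(ssw > 0, ssb / (ssw / (n - 2)),
              ifelse(ssb > 0, Inf, 0))
  ord <- order(-f, seq_along(f))
  .rankedFrame("kbest", colnames(X), f, ord)
}

#' Plug-in mutual information with a binary target
#'
#' Discretizes \code{x} into at most \code{bins} equal-frequency bins and
#' returns the plug-in mutual information (in nats) of the resulting
#' contingency table with \code{y}.
#'
#' @param x numeric vector.
#' @param y binary vector.
#' @param bins number of equal-frequency bins, default 10.
#' @return numeric MI estimate in nats (non-negative).
#' @export
mutualInformation <- function(x, y, bins = 10L) {
  if (!length(x)) stop("empty input")
  .miTable(table(.discretize(x, bins), y))
}

.discretize <- function(x, bins) {
  u <- unique(x)
  if (length(u) <= bins) return(match(x, sort(u)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

.miTable <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  pj <- tab / n
  pr <- rowSums(pj); pc <- colSums(pj)
  e <- outer(pr, pc)
  nz <- pj > 0
  max(0, sum(pj[nz] * log(pj[nz] / e[nz])))
}

# Pairwise / joint MI helpers over pre-discretized columns.
.miXY <- function(dx, y) .miTable(table(dx, y))
.miJoint <- function(dx1, dx2, y) {
  .miTable(table(interaction(dx1, dx2, drop = TRUE), y))
}

#' Greedy MRMR feature selection
#'
#' Minimum-redundancy maximum-relevance (difference variant): the first
#' pick maximizes relevance \eqn{I(X_i; Y)}; each further pick maximizes
#' relevance minus mean mutual information with the already-selected
#' features. Ties break on the lowest feature index.
#'
#' @inheritParams wilcoxonRank
#' @param k number of features to select.
#' @param bins discretization bins for the MI estimates.
#' @return data.frame prefix (rank, feature, score = criterion value at
#'   selection time).
#' @export
mrmrSelect <- function(X, y, k, bins = 10L) {
  k <- as.integer(k)
  if (k <= 0) stop("k must be positive")
  k <- min(k, ncol(X))
  disc <- lapply(seq_len(ncol(X)), function(j) .discretize(X[, j], bins))
  rel <- vapply(disc, .miXY, numeric(1), y = y)
  selected <- integer(0)
  scores <- numeric(0)
  redCache <- matrix(NA_real_, ncol(X), ncol(X))
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    crit <- vapply(cand, function(j) {
      if (!length(selected)) return(rel[j])
      reds <- vapply(selected, function(s) {
        if (is.na(redCache[j, s]))
          redCache[j, s] <<- redCache[s, j] <<-
            .miTable(table(disc[[j]], disc[[s]]))
        redCache[j, s]
      }, numeric(1))
      rel[j] - mean(reds)
    }, numeric(1))
    best <- cand[which.max(crit)]
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
  }
  data.frame(method = "mrmr", rank = seq_along(selected),
             feature = colnames(X)[selected], score = scores,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Greedy JMIM feature selection
#'
#' Joint mutual information maximization: the first pick maximizes
#' \eqn{I(X_i; Y)}; each further pick maximizes the minimum over selected
#' features s of the joint information \eqn{I(X_{cand}, X_s; Y)}. Ties
#' break on the lowest feature index.
#'
#' @inheritParams mrmrSelect
#' @return data.frame prefix as in \code{\link{mrmrSelect}}.
#' @export
jmimSelect <- function(X, y, k, bins = 10L) {
  k <- as.integer(k)
  if (k <= 0) stop("k must be positive")
  k <- min(k, ncol(X))
  disc <- lapply(seq_len(ncol(X)), function(j) .discretize(X[, j], bins))
  rel <- vapply(disc, .miXY, numeric(1), y = y)
  first <- which.max(rel)
  selected <- first
  scores <- rel[first]
  for (step in seq_len(k - 1L)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    crit <- vapply(cand, function(j) {
      min(vapply(selected, function(s)
        .miJoint(disc[[j]], disc[[s]], y), numeric(1)))
    }, numeric(1))
    best <- cand[which.max(crit)]
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
  }
  data.frame(method = "jmim", rank = seq_along(selected),
             feature = colnames(X)[selected], score = scores,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write ranked features to CSV
#'
#' @param ranked data.frame from one of the ranking/selection methods.
#' @param path output file.
#' @export
writeRankedCsv <- function(ranked, path) {
  utils::write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}
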