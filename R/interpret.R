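# Model interpretation: sampling-based Shapley attribution of predictions
# to individual descriptors, and hierarchical clustering of the selected
# features by correlation distance.

#' Sampling-based Shapley feature importance
#'
#' Model-agnostic Shapley attribution by seeded permutation sampling
#' against the marginal background of the reference set: for each probed
#' row, random feature permutations are walked feature-by-feature from a
#' random background row toward the probed row, and each feature is
#' credited with the change in predicted probability it causes. The
#' importance of a feature is the mean absolute attribution over the
#' probed rows. By construction each row's attributions sum to the
#' prediction minus the background expectation (local accuracy, exact per
#' sampled permutation).
#'
#' @param model an \linkS4class{UmamiModel}, \linkS4class{UmamiEnsemble},
#'   or a function mapping a numeric matrix to positive-class
#'   probabilities.
#' @param Xref numeric reference matrix (rows are both the probed points
#'   and the background distribution).
#' @param nSamples permutations sampled per probed row, default 100.
#' @param seed integer seed.
#' @param probeRows optional row indices to probe (defaults to all).
#' @return list: \code{importance} data.frame (rank, feature,
#'   importance), \code{phi} matrix of per-row attributions,
#'   \code{baseline} mean background prediction,
#'   \code{localAccuracyError} max over probed rows of the absolute
#'   local-accuracy gap.
#' @export
shapImportance <- function(model, Xref, nSamples = 100L, seed = 1L,
                           probeRows = NULL) {
  if (nSamples < 1L) stop("nSamples must be at least 1")
  predFun <- if (is.function(model)) model else
    function(X) predictProbability(model, X)
  Xref <- as.matrix(Xref)
  if (!nrow(Xref)) stop("empty reference set")
  nF <- ncol(Xref)
  feats <- colnames(Xref)
  if (is.null(probeRows)) probeRows <- seq_len(nrow(Xref))

  phi <- matrix(0, length(probeRows), nF,
                dimnames = list(rownames(Xref)[probeRows], feats))
  fx <- predFun(Xref[probeRows, , drop = FALSE])
  baselineAll <- predFun(Xref)
  baseline <- mean(baselineAll)
  gaps <- numeric(length(probeRows))

  .withSeed(seed, {
    for (ri in seq_along(probeRows)) {
      x <- Xref[probeRows[ri], ]
      acc <- numeric(nF)
      gap <- 0
      for (s in seq_len(nSamples)) {
        z <- Xref[sample.int(nrow(Xref), 1L), ]
        perm <- sample.int(nF)
        # build the chain z -> x one feature at a time; F+1 predictions
        chain <- matrix(rep(z, nF + 1L), nF + 1L, nF, byrow = TRUE)
        cur <- z
        for (step in seq_len(nF)) {
          cur[perm[step]] <- x[perm[step]]
          chain[step + 1L, ] <- cur
        }
        colnames(chain) <- feats
        pr <- predFun(chain)
        acc[perm] <- acc[perm] + diff(pr)
        gap <- gap + (pr[1])  # background prediction of this permutation
      }
      phi[ri, ] <- acc / nSamples
      # local accuracy vs the per-row sampled background mean
      gaps[ri] <- abs(sum(phi[ri, ]) - (fx[ri] - gap / nSamples))
    }
  })

  imp <- colMeans(abs(phi))
  ord <- order(-imp, feats)
  list(importance = data.frame(rank = seq_len(nF), feature = feats[ord],
                               importance = unname(imp[ord]),
                               row.names = NULL),
       phi = phi, baseline = baseline,
       localAccuracyError = max(gaps))
}

#' Hierarchical clustering of selected features
#'
#' Agglomerative clustering of the feature columns with correlation
#' distance \eqn{1 - |r|} (Pearson) and average linkage; constant
#' features sit at distance 1 from everything.
#'
#' @param X numeric matrix of the selected features (columns).
#' @param nGroups flat groups to cut, default 3.
#' @return list: \code{hclust} (dendrogram object), \code{groups} (named
#'   integer vector of flat group ids).
#' @export
clusterFeatures <- function(X, nGroups = 3L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 features")
  r <- suppressWarnings(stats::cor(X))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  groups <- stats::cutree(hc, k = min(nGroups, ncol(X)))
  list(hclust = hc, groups = groups)
}

#' Write an importance table as CSV (rank, feature, importance)
#'
#' @param importance data.frame from \code{\link{shapImportance}}.
#' @param path output file.
#' @export
writeImportanceCsv <- function(importance, path) {
  utils::write.csv(importance, path, row.names = FALSE)
  invisible(path)
}
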