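# Two-model ensembles: class probabilities are averaged and the predicted
# class is the arg-max, with a tie at exactly 0.5 resolved to non-umami
# (the conservative call for a screening tool).

#' Build a two-model ensemble
#'
#' @param memberA,memberB trained \linkS4class{UmamiModel} objects fitted
#'   on the same preprocessed feature space.
#' @param tag provenance tag, e.g. \code{"EM_3-5"}.
#' @return An \linkS4class{UmamiEnsemble}.
#' @export
makeEnsemble <- function(memberA, memberB, tag = "") {
  new("UmamiEnsemble", memberA = memberA, memberB = memberB, tag = tag)
}

#' Ensemble prediction
#'
#' Averages the umami probability of the two members and derives the
#' class; a probability of exactly 0.5 is called non-umami.
#'
#' @param em an \linkS4class{UmamiEnsemble}.
#' @param X preprocessed descriptor matrix.
#' @return list with \code{probUmami} and \code{class} (integer 0/1).
#' @export
ensemblePredict <- function(em, X) {
  stopifnot(is(em, "UmamiEnsemble"))
  p <- predictProbability(em, X)
  list(probUmami = p, class = as.integer(p > 0.5))
}

#' Select the best two-model ensemble
#'
#' Evaluates every pair among the candidate models by cross-validated
#' scalarized score — per fold both members are refitted on the
#' oversampled training folds, their held-out probabilities averaged and
#' scored — and returns the winning pair plus the full comparison table.
#'
#' @param candidates list of model specs (decoded lists with
#'   \code{features}, \code{classifier}, hyperparameters) or archive
#'   members carrying a \code{spec} element.
#' @param X preprocessed training matrix.
#' @param y binary labels.
#' @param cv CV plan from \code{\link{makeCvPlan}}.
#' @param weights \code{\link{goalWeights}}.
#' @param seed integer seed for the final member fits.
#' @return list: \code{ensemble} (\linkS4class{UmamiEnsemble} fitted on
#'   the full training split), \code{table} (per-pair CV metrics),
#'   \code{bestPair} indices.
#' @export
selectBestEnsemble <- function(candidates, X, y, cv,
                               weights = goalWeights(), seed = 1L) {
  specs <- lapply(candidates, function(c)
    if (!is.null(c$spec)) c$spec else c)
  n <- length(specs)
  if (n < 2L) stop("need at least 2 candidate models")
  pairs <- utils::combn(n, 2)
  rows <- vector("list", ncol(pairs))
  for (pIdx in seq_len(ncol(pairs))) {
    a <- pairs[1, pIdx]; b <- pairs[2, pIdx]
    fit <- .ensembleCvFitness(specs[[a]], specs[[b]], X, y, cv)
    rows[[pIdx]] <- data.frame(
      pair = sprintf("EM_%d-%d", a, b), memberA = a, memberB = b,
      acc = fit["acc"], prc = fit["prc"], rec = fit["rec"],
      f1 = fit["f1"], f2 = fit["f2"], auc = fit["auc"],
      scalar = scalarize(fit, weights), row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  bi <- order(-tab$scalar, tab$pair)[1]
  a <- tab$memberA[bi]; b <- tab$memberB[bi]
  em <- makeEnsemble(
    trainFinal(specs[[a]], X, y, seed = .childSeed(seed, "memA", a),
               tag = sprintf("model_%d", a)),
    trainFinal(specs[[b]], X, y, seed = .childSeed(seed, "memB", b),
               tag = sprintf("model_%d", b)),
    tag = tab$pair[bi])
  list(ensemble = em, table = tab, bestPair = c(a, b))
}

# CV fitness of a member pair: both refitted per fold, probabilities
# averaged on the untouched evaluation fold. detail=TRUE also returns the
# per-fold metric matrix (for mean +/- sd reporting).
.ensembleCvFitness <- function(specA, specB, X, y, cv, detail = FALSE) {
  comp <- matrix(NA_real_, length(cv$folds), 7)
  specCol <- numeric(length(cv$folds))
  featFrac <- (length(union(specA$features, specB$features))) / ncol(X)
  sizeFracs <- numeric(length(cv$folds))
  for (f in seq_along(cv$folds)) {
    testIdx <- cv$folds[[f]]
    trainIdx <- cv$trainIndex[[f]]
    pm <- lapply(list(specA, specB), function(sp) {
      fitRes <- .fitClassifier(sp, X[trainIdx, sp$features, drop = FALSE],
                               y[trainIdx], seed = cv$foldSeeds[f])
      list(p = .predictProb(fitRes, X[testIdx, sp$features, drop = FALSE]),
           sizeFrac = fitRes$sizeFrac)
    })
    p <- (pm[[1]]$p + pm[[2]]$p) / 2
    m <- computeMetrics(y[testIdx], p)
    comp[f, ] <- c(m$acc, m$prc, m$rec, m$f1, m$f2,
                   if (is.na(m$auc)) 0.5 else m$auc, 0)
    specCol[f] <- if (is.na(m$spec)) 1 else m$spec
    sizeFracs[f] <- min(1, mean(c(pm[[1]]$sizeFrac, pm[[2]]$sizeFrac)))
  }
  means <- colMeans(comp)
  fit <- stats::setNames(c(means[1:6], min(1, featFrac), mean(sizeFracs)),
                         .FITNESS_NAMES)
  if (!detail) return(fit)
  perFold <- cbind(comp[, 1, drop = FALSE], specCol,
                   comp[, 2:6, drop = FALSE])
  colnames(perFold) <- c("acc", "spec", "prc", "rec", "f1", "f2", "auc")
  list(fitness = fit, perFold = perFold)
}
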