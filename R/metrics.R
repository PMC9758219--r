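# Binary-classification metrics: confusion counts at a probability
# threshold, the derived rates, F-beta scores, and a rank-based AUC with
# ties counted one half.

#' Classification metrics from probabilities
#'
#' Confusion counts at \code{threshold} on the positive-class probability
#' plus accuracy, specificity, sensitivity (= recall), precision, F1, F2
#' and the rank-based AUC (concordance of positive-class probabilities;
#' ties count 0.5). With a single-class truth vector the AUC is undefined
#' and reported as NA.
#'
#' @param yTrue binary labels (1 = positive/umami).
#' @param pPos positive-class probabilities in [0, 1].
#' @param threshold classification threshold, default 0.5; a probability
#'   strictly greater than the threshold predicts the positive class.
#' @return named list: TP, FP, TN, FN, acc, spec, sens, prc, rec, f1, f2,
#'   auc.
#' @examples
#' computeMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
#' @export
computeMetrics <- function(yTrue, pPos, threshold = 0.5) {
  yTrue <- as.integer(yTrue)
  stopifnot(length(yTrue) == length(pPos))
  pred <- as.integer(pPos > threshold)
  tp <- sum(pred == 1L & yTrue == 1L)
  fp <- sum(pred == 1L & yTrue == 0L)
  tn <- sum(pred == 0L & yTrue == 0L)
  fn <- sum(pred == 0L & yTrue == 1L)
  n <- length(yTrue)
  prc <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    acc = (tp + tn) / n,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sens = rec, prc = prc, rec = rec,
    f1 = if (prc + rec > 0) 2 * prc * rec / (prc + rec) else 0,
    f2 = if (4 * prc + rec > 0) 5 * prc * rec / (4 * prc + rec) else 0,
    auc = aucRank(yTrue, pPos)
  )
}

#' Rank-based AUC
#'
#' Mann-Whitney concordance: the probability that a random positive is
#' scored above a random negative, ties counting one half, computed from
#' mid-ranks.
#'
#' @inheritParams computeMetrics
#' @return numeric AUC, or NA when only one class is present.
#' @export
aucRank <- function(yTrue, pPos) {
  yTrue <- as.integer(yTrue)
  nPos <- sum(yTrue == 1L); nNeg <- sum(yTrue == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(pPos, ties.method = "average")
  (sum(r[yTrue == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
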