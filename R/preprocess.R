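# Preprocessing: missing-value filtering, kNN imputation, [0,1] min-max
# normalization, minority oversampling and stratified folds. The pipeline
# order is fixed (filter -> impute -> normalize) and all parameters are
# learned on the training split only, then frozen.

#' Drop features with too many missing values
#'
#' Removes every feature whose missing fraction is strictly greater than
#' \code{maxMissingFrac}; survivor order is preserved.
#'
#' @param dt a \linkS4class{DescriptorTable} (unnormalized).
#' @param maxMissingFrac threshold fraction, default 0.30.
#' @return list with \code{table} (filtered \linkS4class{DescriptorTable})
#'   and \code{dropped} (character vector of removed features).
#' @export
filterMissing <- function(dt, maxMissingFrac = 0.30) {
  stopifnot(is(dt, "DescriptorTable"))
  if (isTRUE(dt@normalized)) stop("filterMissing expects an unnormalized table")
  frac <- colMeans(dt@missing)
  keep <- frac <= maxMissingFrac
  if (!any(keep)) stop("all features exceed the missing-value threshold")
  list(table = .DescriptorTable(dt@values[, keep, drop = FALSE]),
       dropped = colnames(dt@values)[!keep])
}

#' k-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean of that feature over the k
#' rows nearest in Euclidean distance, computed on the features observed
#' in both rows and scaled by the number of shared features. Rows with
#' fewer than k candidate neighbours (neighbours must observe the target
#' feature) use all available. Observed cells never change.
#'
#' @param dt a \linkS4class{DescriptorTable}.
#' @param k number of neighbours, default 20.
#' @return An imputed \linkS4class{DescriptorTable} with no missing cells.
#' @export
knnImpute <- function(dt, k = 20L) {
  stopifnot(is(dt, "DescriptorTable"))
  X <- dt@values
  M <- dt@missing
  if (!any(M)) return(dt)
  n <- nrow(X)
  zeroObs <- which(rowSums(!M) == 0L)
  if (length(zeroObs))
    stop("row(s) with zero observed features: ",
         paste(rownames(X)[zeroObs], collapse = ", "))

  # pairwise mean squared difference over mutually observed features
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- !M[i, ] & !M[j, ]
      if (any(shared)) {
        d <- X[i, shared] - X[j, shared]
        D[i, j] <- D[j, i] <- sum(d * d) / sum(shared)
      }
    }
  }

  out <- X
  for (i in seq_len(n)) {
    miss <- which(M[i, ])
    if (!length(miss)) next
    ord <- order(D[i, ])
    ord <- ord[ord != i & is.finite(D[i, ord])]
    for (f in miss) {
      cand <- ord[!M[ord, f]]
      if (!length(cand)) {
        out[i, f] <- mean(X[!M[, f], f])  # fall back to feature mean
      } else {
        out[i, f] <- mean(X[utils::head(cand, k), f])
      }
    }
  }
  .DescriptorTable(out)
}

#' Fit min-max normalization parameters on a training table
#'
#' Learns per-feature minima and maxima (and records the missing-filter
#' and imputation settings) once; \code{\link{applyMinmax}} then maps any
#' table into \eqn{[0, 1]} with those frozen parameters.
#'
#' @param dt an imputed \linkS4class{DescriptorTable}.
#' @param maxMissingFrac,knnK recorded provenance of earlier steps.
#' @param seed integer recorded for the run log.
#' @return A \linkS4class{PreprocessParams}.
#' @export
fitMinmax <- function(dt, maxMissingFrac = 0.30, knnK = 20L, seed = NA) {
  stopifnot(is(dt, "DescriptorTable"))
  if (any(dt@missing)) stop("fit requires an imputed (complete) table")
  mins <- apply(dt@values, 2, min)
  maxs <- apply(dt@values, 2, max)
  new("PreprocessParams", maxMissingFrac = maxMissingFrac,
      knnK = as.integer(knnK), keptFeatures = colnames(dt@values),
      featureMin = mins, featureMax = maxs, fitted = TRUE,
      seed = as.integer(seed))
}

#' Apply frozen min-max normalization
#'
#' Maps \code{x} to \code{(x - min) / (max - min)} per feature with the
#' training ranges; constant features map to 0 and out-of-range values on
#' new data are clipped to \eqn{[0, 1]}.
#'
#' @param dt a \linkS4class{DescriptorTable} restricted (or restrictable)
#'   to the fitted feature set.
#' @param params a fitted \linkS4class{PreprocessParams}.
#' @return A normalized \linkS4class{DescriptorTable}.
#' @export
applyMinmax <- function(dt, params) {
  stopifnot(is(dt, "DescriptorTable"), is(params, "PreprocessParams"))
  if (!isTRUE(params@fitted)) stop("normalization applied before fit")
  feats <- params@keptFeatures
  miss <- setdiff(feats, colnames(dt@values))
  if (length(miss))
    stop("table lacks fitted feature(s): ", paste(miss, collapse = ", "))
  X <- dt@values[, feats, drop = FALSE]
  rng <- params@featureMax - params@featureMin
  for (j in seq_along(feats)) {
    if (rng[j] <= 0) {
      X[, j] <- ifelse(is.na(X[, j]), NA_real_, 0)
    } else {
      X[, j] <- (X[, j] - params@featureMin[j]) / rng[j]
      X[, j] <- pmin(pmax(X[, j], 0), 1)
    }
  }
  .DescriptorTable(X, normalized = TRUE,
                   normParams = list(min = params@featureMin,
                                     max = params@featureMax))
}

#' Random oversampling of the minority class
#'
#' Duplicates minority-class rows by seeded sampling with replacement
#' until the class counts are equal. All original rows are retained and
#' the majority class is untouched.
#'
#' @param X numeric matrix (rows = samples).
#' @param y binary labels (0/1).
#' @param seed integer seed.
#' @return list with \code{X}, \code{y} and \code{index} (row indices into
#'   the input, duplicates included).
#' @export
randomOversample <- function(X, y, seed = 1L) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("both classes must be present")
  minor <- as.integer(names(tab)[which.min(tab)])
  need <- abs(diff(as.integer(tab)))
  idx <- seq_along(y)
  if (need > 0) {
    pool <- which(y == minor)
    extra <- if (length(pool) == 1L) rep(pool, need) else
      .withSeed(seed, sample(pool, need, replace = TRUE))
    idx <- c(idx, extra)
  }
  list(X = X[idx, , drop = FALSE], y = y[idx], index = idx)
}

#' Stratified k-fold assignment
#'
#' Partitions sample indices into \code{nFolds} folds with per-class
#' counts differing by at most one between folds, shuffled under the seed.
#'
#' @param y binary labels.
#' @param nFolds number of folds, default 10.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..nFolds) per sample.
#' @export
stratifiedKfold <- function(y, nFolds = 10L, seed = 1L) {
  y <- as.integer(y)
  n <- length(y)
  if (nFolds > n) stop("more folds than samples")
  fold <- integer(n)
  .withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

# Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Derive a reproducible child seed from a base seed and stream labels.
.childSeed <- function(seed, ...) {
  parts <- c(as.integer(seed), vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.integer(p)
  }, integer(1)))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(s)
}
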