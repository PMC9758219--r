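#' @import methods
NULL

#' Set of molecules with labels and split assignment
#'
#' Container for a labeled molecular dataset: one row per molecule with its
#' original notation, the standardized canonical SMILES, structure-checker
#' issue level and exclusion flag, plus a binary umami label (1 = umami,
#' 0 = non-umami) and a train/test split tag per molecule.
#'
#' @slot records data.frame with columns \code{id}, \code{source_text},
#'   \code{notation}, \code{canonical_smiles}, \code{issue_level},
#'   \code{excluded}, \code{message}.
#' @slot labels integer vector of 0/1 labels, same length as rows of
#'   \code{records} (NA allowed for unlabeled query sets).
#' @slot split character vector, one of \code{"train"}, \code{"test"},
#'   \code{"unassigned"} per molecule.
#'
#' @export
setClass("MoleculeSet",
  representation(records = "data.frame", labels = "integer",
                 split = "character"),
  prototype(records = data.frame(), labels = integer(0),
            split = character(0))
)

setValidity("MoleculeSet", function(object) {
  msgs <- character(0)
  req <- c("id", "source_text", "notation", "canonical_smiles",
           "issue_level", "excluded", "message")
  if (!all(req %in% names(object@records)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(req, collapse = ", ")))
  n <- nrow(object@records)
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels length must equal number of records")
  if (length(object@split) != n)
    msgs <- c(msgs, "split length must equal number of records")
  if (n > 0) {
    bad <- !object@split %in% c("train", "test", "unassigned")
    if (any(bad)) msgs <- c(msgs, "split tags must be train/test/unassigned")
    lab <- object@labels
    if (any(!is.na(lab) & !lab %in% c(0L, 1L)))
      msgs <- c(msgs, "labels must be 0, 1 or NA")
    # canonical SMILES non-empty iff not excluded
    r <- object@records
    if (any(!r$excluded & !nzchar(r$canonical_smiles)))
      msgs <- c(msgs, "non-excluded records must carry a canonical SMILES")
  }
  if (length(msgs)) msgs else TRUE
})

#' Molecules-by-descriptors matrix with missing mask
#'
#' Numeric matrix of 2D molecular descriptors (rows = molecules, columns =
#' named descriptors) together with a logical missing mask, a normalization
#' flag and, once min-max parameters have been fitted and applied, the
#' per-feature ranges used.
#'
#' @slot values numeric matrix, molecules x features, with NA at missing
#'   cells.
#' @slot missing logical matrix, same dimensions, TRUE where the descriptor
#'   value is undefined.
#' @slot normalized logical scalar.
#' @slot normParams list with elements \code{min} and \code{max} (named
#'   numeric vectors) when fitted, else empty list.
#'
#' @export
setClass("DescriptorTable",
  representation(values = "matrix", missing = "matrix",
                 normalized = "logical", normParams = "list"),
  prototype(values = matrix(numeric(0), 0, 0),
            missing = matrix(logical(0), 0, 0),
            normalized = FALSE, normParams = list())
)

setValidity("DescriptorTable", function(object) {
  msgs <- character(0)
  if (!all(dim(object@values) == dim(object@missing)))
    msgs <- c(msgs, "values and missing mask must share dimensions")
  if (is.null(colnames(object@values)) && ncol(object@values) > 0)
    msgs <- c(msgs, "values must carry feature names")
  if (any(is.na(object@values) != object@missing))
    msgs <- c(msgs, "missing mask must be TRUE exactly where values are NA")
  if (isTRUE(object@normalized)) {
    v <- object@values[!object@missing]
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
      msgs <- c(msgs, "normalized values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Frozen preprocessing parameters
#'
#' Missing-value filter threshold, kNN-imputation k, the surviving feature
#' list and the per-feature min/max learned on the training split. Learned
#' once, then applied unchanged to any later table.
#'
#' @slot maxMissingFrac numeric, features missing in more than this
#'   fraction of molecules are dropped (default 0.30).
#' @slot knnK integer, neighbours for kNN imputation (default 20).
#' @slot keptFeatures character, features surviving the missing filter.
#' @slot featureMin,featureMax named numeric vectors of training ranges.
#' @slot fitted logical.
#' @slot seed integer seed recorded at fit time.
#'
#' @export
setClass("PreprocessParams",
  representation(maxMissingFrac = "numeric", knnK = "integer",
                 keptFeatures = "character", featureMin = "numeric",
                 featureMax = "numeric", fitted = "logical",
                 seed = "integer"),
  prototype(maxMissingFrac = 0.30, knnK = 20L, keptFeatures = character(0),
            featureMin = numeric(0), featureMax = numeric(0),
            fitted = FALSE, seed = NA_integer_)
)

#' Empirical-Bayes variance prior
#'
#' Prior degrees of freedom and prior variance for the moderated t-test,
#' estimated by moment matching of log sample variances.
#'
#' @slot d0 numeric prior degrees of freedom (Inf when the variance
#'   dispersion is at or below its theoretical minimum).
#' @slot s0sq numeric prior variance.
#'
#' @export
setClass("EBayesPrior",
  representation(d0 = "numeric", s0sq = "numeric"),
  prototype(d0 = NA_real_, s0sq = NA_real_)
)

setValidity("EBayesPrior", function(object) {
  if (!is.na(object@s0sq) && object@s0sq <= 0)
    return("s0sq must be positive")
  if (!is.na(object@d0) && object@d0 <= 0)
    return("d0 must be positive (possibly Inf)")
  TRUE
})

#' Fingerprint applicability domain
#'
#' Training-set Morgan fingerprints plus the average-top-k Tanimoto
#' similarity rule that decides whether a query molecule falls inside the
#' model's applicability domain.
#'
#' @slot fps logical matrix, one row per training molecule, 1024 columns by
#'   default.
#' @slot ids character molecule identifiers.
#' @slot kTop integer, number of most-similar training compounds averaged
#'   (default 5).
#' @slot threshold numeric in (0, 1], minimum average similarity to be
#'   inside the domain (default 0.4).
#' @slot nbits,radius fingerprint parameters.
#'
#' @export
setClass("ADModel",
  representation(fps = "matrix", ids = "character", kTop = "integer",
                 threshold = "numeric", nbits = "integer",
                 radius = "integer"),
  prototype(kTop = 5L, threshold = 0.4, nbits = 1024L, radius = 2L)
)

setValidity("ADModel", function(object) {
  msgs <- character(0)
  if (nrow(object@fps) != length(object@ids))
    msgs <- c(msgs, "one id per fingerprint row required")
  if (!(object@threshold > 0 && object@threshold <= 1))
    msgs <- c(msgs, "threshold must lie in (0, 1]")
  if (ncol(object@fps) > 0 && ncol(object@fps) != object@nbits)
    msgs <- c(msgs, "fingerprint width must equal nbits")
  if (length(msgs)) msgs else TRUE
})

#' Trained single classifier
#'
#' One decoded model: selected feature subset, classifier family and
#' hyperparameters, the fitted classifier and (for SVM) the deterministic
#' logistic calibration mapping decision values to probabilities.
#'
#' @slot features character, selected descriptor names.
#' @slot classifier \code{"svm"} or \code{"rf"}.
#' @slot hyper named list (C, gamma for SVM; ntrees for RF).
#' @slot fit the fitted classifier object.
#' @slot calibration numeric length-2 (intercept, slope) of the Platt-style
#'   logistic calibration for SVM decision values; ignored for RF.
#' @slot seed integer seed used for fitting.
#' @slot tag character provenance tag.
#'
#' @export
setClass("UmamiModel",
  representation(features = "character", classifier = "character",
                 hyper = "list", fit = "ANY", calibration = "numeric",
                 seed = "integer", tag = "character"),
  prototype(calibration = c(0, 1), seed = NA_integer_, tag = "")
)

#' Two-model probability-averaging ensemble
#'
#' Pair of trained models whose class probabilities are averaged; the
#' predicted class is the arg-max, with a tie at exactly 0.5 resolved to
#' non-umami.
#'
#' @slot memberA,memberB \linkS4class{UmamiModel} members.
#' @slot tag character provenance tag such as \code{"EM_1-2"}.
#'
#' @export
setClass("UmamiEnsemble",
  representation(memberA = "UmamiModel", memberB = "UmamiModel",
                 tag = "character"),
  prototype(tag = "")
)

## ---- show methods ----

setMethod("show", "MoleculeSet", function(object) {
  n <- nrow(object@records)
  cat("MoleculeSet with", n, "molecules\n")
  if (n) {
    cat("  excluded:", sum(object@records$excluded), "\n")
    lab <- object@labels
    cat("  labels: ", sum(lab == 1L, na.rm = TRUE), " umami, ",
        sum(lab == 0L, na.rm = TRUE), " non-umami, ",
        sum(is.na(lab)), " unlabeled\n", sep = "")
    cat("  split:  ", sum(object@split == "train"), " train / ",
        sum(object@split == "test"), " test / ",
        sum(object@split == "unassigned"), " unassigned\n", sep = "")
  }
})

setMethod("show", "DescriptorTable", function(object) {
  cat("DescriptorTable:", nrow(object@values), "molecules x",
      ncol(object@values), "descriptors\n")
  cat("  missing cells:", sum(object@missing),
      if (isTRUE(object@normalized)) " (normalized to [0,1])" else "", "\n",
      sep = "")
})

setMethod("show", "EBayesPrior", function(object) {
  cat("EBayesPrior: d0 =", format(object@d0), ", s0^2 =",
      format(object@s0sq), "\n")
})

setMethod("show", "ADModel", function(object) {
  cat("ADModel:", nrow(object@fps), "training fingerprints (",
      object@nbits, "bits, radius", object@radius, ")\n")
  cat("  rule: mean of top-", object@kTop, " Tanimoto >= ",
      object@threshold, "\n", sep = "")
})

setMethod("show", "UmamiModel", function(object) {
  cat("UmamiModel [", object@classifier, "] ",
      length(object@features), " features", sep = "")
  if (nzchar(object@tag)) cat("  (", object@tag, ")", sep = "")
  cat("\n")
})

setMethod("show", "UmamiEnsemble", function(object) {
  cat("UmamiEnsemble", if (nzchar(object@tag)) object@tag else "", "\n")
  cat("  A:"); show(object@memberA)
  cat("  B:"); show(object@memberB)
})

## ---- accessors ----

#' Accessors for package containers
#'
#' Small accessor family: molecule records/labels/split of a
#' \linkS4class{MoleculeSet}; values, missing mask, feature names and
#' molecule ids of a \linkS4class{DescriptorTable}; threshold of an
#' \linkS4class{ADModel}.
#'
#' @param x the object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
molRecords <- function(x) { stopifnot(is(x, "MoleculeSet")); x@records }

#' @rdname accessors
#' @export
molLabels <- function(x) { stopifnot(is(x, "MoleculeSet")); x@labels }

#' @rdname accessors
#' @export
molSplit <- function(x) { stopifnot(is(x, "MoleculeSet")); x@split }

#' @rdname accessors
#' @export
descValues <- function(x) { stopifnot(is(x, "DescriptorTable")); x@values }

#' @rdname accessors
#' @export
missingMask <- function(x) { stopifnot(is(x, "DescriptorTable")); x@missing }

#' @rdname accessors
#' @export
descFeatureNames <- function(x) {
  stopifnot(is(x, "DescriptorTable")); colnames(x@values)
}

#' @rdname accessors
#' @export
descMoleculeIds <- function(x) {
  stopifnot(is(x, "DescriptorTable")); rownames(x@values)
}

#' @rdname accessors
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "DescriptorTable")); isTRUE(x@normalized)
}

#' @rdname accessors
#' @export
adThreshold <- function(x) { stopifnot(is(x, "ADModel")); x@threshold }

#' @rdname accessors
#' @export
modelFeatures <- function(x) {
  if (is(x, "UmamiEnsemble"))
    return(sort(union(x@memberA@features, x@memberB@features)))
  stopifnot(is(x, "UmamiModel")); x@features
}

# internal constructor helper
.DescriptorTable <- function(values, normalized = FALSE,
                             normParams = list()) {
  new("DescriptorTable", values = values, missing = is.na(values),
      normalized = normalized, normParams = normParams)
}
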