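# Classifier backends for the optimizer: RBF support vector machines
# (e1071/libsvm) and random forests. SVM class probabilities come from a
# deterministic logistic (Platt-style) calibration of the decision values
# fitted on the training data, which keeps identical seeds byte-identical
# across runs; random-forest probabilities are vote fractions under a
# seeded fit.

# Fit one classifier on (X, y). spec: list(classifier, C, gamma, ntrees).
.fitClassifier <- function(spec, X, y, seed = 1L) {
  y <- as.integer(y)
  if (spec$classifier == "svm") {
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                      kernel = "radial", cost = spec$C,
                      gamma = spec$gamma, scale = FALSE)
    dv <- .svmDecision(fit, X)
    calib <- .plattFit(dv, y)
    list(classifier = "svm", fit = fit, calibration = calib,
         size = sum(fit$nSV), sizeFrac = sum(fit$nSV) / nrow(X))
  } else {
    fit <- .withSeed(seed,
      randomForest::randomForest(x = X,
                                 y = factor(y, levels = c(0L, 1L)),
                                 ntree = spec$ntrees))
    list(classifier = "rf", fit = fit, calibration = c(0, 1),
         size = spec$ntrees, sizeFrac = (spec$ntrees - 10) / 490)
  }
}

# Decision value oriented so that larger = more likely class "1".
.svmDecision <- function(fit, X) {
  dvm <- attr(stats::predict(fit, X, decision.values = TRUE),
              "decision.values")
  dv <- dvm[, 1]
  # libsvm orients the decision by label order of appearance; the column
  # name "0/1" means positive values favour class "0"
  if (identical(colnames(dvm)[1], "0/1")) dv <- -dv
  dv
}

# Logistic calibration of decision values; deterministic. Guarded against
# perfect separation (glm still converges to a steep but finite sigmoid
# under its iteration cap).
.plattFit <- function(dv, y) {
  if (length(unique(y)) < 2L) return(c(0, 1))
  co <- tryCatch(suppressWarnings(
    stats::glm.fit(cbind(1, dv), y,
                   family = stats::binomial())$coefficients),
    error = function(e) c(0, 1))
  if (any(!is.finite(co))) co <- c(0, 1)
  co
}

# Positive-class probability from a fitted backend. The "fixed" backend
# carries a plain function(X) -> probability (constant baselines, mocks).
.predictProb <- function(model, X) {
  X <- as.matrix(X)
  if (model$classifier == "fixed") return(model$fit(X))
  if (model$classifier == "svm") {
    dv <- .svmDecision(model$fit, X)
    stats::plogis(model$calibration[1] + model$calibration[2] * dv)
  } else {
    stats::predict(model$fit, X, type = "prob")[, "1"]
  }
}

#' Predicted umami probability
#'
#' Positive-class (umami) probability for new samples from a trained
#' single model or a two-model ensemble.
#'
#' @param object an \linkS4class{UmamiModel} or
#'   \linkS4class{UmamiEnsemble}.
#' @param X numeric matrix of preprocessed descriptors containing at
#'   least the model's selected features.
#' @return numeric vector of probabilities.
#' @export
setGeneric("predictProbability", function(object, X)
  standardGeneric("predictProbability"))

#' @rdname predictProbability
setMethod("predictProbability", "UmamiModel", function(object, X) {
  miss <- setdiff(object@features, colnames(X))
  if (length(miss))
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "))
  .predictProb(list(classifier = object@classifier, fit = object@fit,
                    calibration = object@calibration),
               X[, object@features, drop = FALSE])
})

#' @rdname predictProbability
setMethod("predictProbability", "UmamiEnsemble", function(object, X) {
  (predictProbability(object@memberA, X) +
     predictProbability(object@memberB, X)) / 2
})
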