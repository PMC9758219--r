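# End-to-end training, prediction and screening: the workflow behind the
# command-line entry points. A trained model is stored as a plain-text
# bundle directory (preprocessing parameters, the preprocessed training
# matrix, member specifications, AD fingerprints, metrics table) from
# which the classifiers are refitted deterministically on load.

#' Train the full umami classification pipeline
#'
#' Standardizes the labeled input molecules, computes descriptors on the
#' training split, preprocesses (missing filter, kNN imputation, min-max
#' normalization), prioritizes features with the moderated t-test at
#' q <= 0.05, runs the evolutionary model search, builds the best
#' two-model ensemble from the top archive members, fits the
#' applicability domain and evaluates on the held-out test split.
#'
#' @param data a \linkS4class{MoleculeSet} or a path to a dataset CSV
#'   (\code{\link{readLabeledDataset}} schema).
#' @param outDir optional directory to write the model bundle to.
#' @param config an \code{\link{optimizerConfig}}; its seed drives every
#'   random choice in the pipeline.
#' @param weights \code{\link{goalWeights}}.
#' @param qThreshold prioritization cutoff, default 0.05.
#' @param minPrioritized minimum candidate features for the search; when
#'   fewer pass the q filter the smallest-q features top the list up.
#' @param testFraction held-out fraction when the input has no split
#'   tags, default 0.2.
#' @param nEnsembleCandidates archive members considered for pairing,
#'   default 5.
#' @param adThreshold applicability-domain threshold, default 0.4.
#' @return list of class \code{"umamiBundle"}: \code{params}
#'   (\linkS4class{PreprocessParams}), \code{ensemble}, \code{ad},
#'   \code{archive}, \code{stats}, \code{metricsTable}, \code{trainX},
#'   \code{trainY}, \code{config}, \code{weights}, \code{comparison}.
#' @export
trainUmamiModel <- function(data, outDir = NULL,
                            config = optimizerConfig(),
                            weights = goalWeights(), qThreshold = 0.05,
                            minPrioritized = 5L, testFraction = 0.2,
                            nEnsembleCandidates = 5L, adThreshold = 0.4) {
  ms <- if (is(data, "MoleculeSet")) data else
    readLabeledDataset(data, format = "csv")
  recs <- molRecords(ms)
  keep <- !recs$excluded & !is.na(molLabels(ms))
  if (!any(keep)) stop("no usable labeled molecules after standardization")
  smiles <- recs$canonical_smiles[keep]
  ids <- recs$id[keep]
  y <- molLabels(ms)[keep]
  split <- molSplit(ms)[keep]

  if (!any(split == "train")) {
    split <- .assignSplit(y, testFraction, seed = config$seed)
  }
  trIdx <- which(split == "train")
  teIdx <- which(split == "test")
  if (length(unique(y[trIdx])) < 2L)
    stop("training split must contain both classes")

  dt <- computeDescriptors(smiles[trIdx], ids = ids[trIdx])
  flt <- filterMissing(dt, maxMissingFrac = 0.30)
  imp <- knnImpute(flt$table, k = 20L)
  params <- fitMinmax(imp, seed = config$seed)
  norm <- applyMinmax(imp, params)
  Xtr <- descValues(norm)
  ytr <- y[trIdx]

  st <- featureStats(Xtr, ytr, qThreshold = qThreshold)
  prio <- prioritizeFeatures(st, qThreshold = qThreshold)
  if (length(prio) < minPrioritized) {
    extra <- st$feature[order(st$q, -abs(st$log2FC), st$feature)]
    prio <- utils::head(unique(c(prio, extra)), minPrioritized)
  }
  Xcand <- Xtr[, prio, drop = FALSE]

  archive <- evolveModels(Xcand, ytr, config = config, weights = weights)
  nCand <- min(nEnsembleCandidates, length(archive$members))
  if (nCand >= 2L) {
    sel <- selectBestEnsemble(archive$members[seq_len(nCand)], Xcand, ytr,
                              archive$cv, weights = weights,
                              seed = config$seed)
    ensemble <- sel$ensemble
    comparison <- sel$table
  } else {
    # degenerate archive: pair the single member with itself
    m <- trainFinal(archive$members[[1]]$spec, Xcand, ytr,
                    seed = config$seed, tag = "model_1")
    ensemble <- makeEnsemble(m, m, tag = "EM_1-1")
    comparison <- NULL
  }

  ad <- fitAD(smiles[trIdx], ids = ids[trIdx], threshold = adThreshold)

  metricsTable <- .metricsTableFor(ensemble, Xcand, ytr, archive$cv,
                                   smiles, ids, y, teIdx, params)

  bundle <- list(params = params, ensemble = ensemble, ad = ad,
                 archive = archive, stats = st,
                 prioritized = prio, metricsTable = metricsTable,
                 trainX = Xcand, trainY = ytr, config = config,
                 weights = weights, comparison = comparison)
  class(bundle) <- "umamiBundle"
  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

.assignSplit <- function(y, testFraction, seed) {
  split <- rep("train", length(y))
  .withSeed(.childSeed(seed, "split"), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nTest <- round(testFraction * length(idx))
      if (nTest > 0) split[sample(idx, nTest)] <- "test"
    }
  })
  split
}

# Metrics table in the three-row layout: training (fit on oversampled
# training data, scored on it), 10-fold CV mean +/- sd, held-out test.
.metricsTableFor <- function(ensemble, Xcand, ytr, cv, smiles, ids, y,
                             teIdx, params) {
  specA <- .specOf(ensemble@memberA)
  specB <- .specOf(ensemble@memberB)
  cvRes <- .ensembleCvFitness(specA, specB, Xcand, ytr, cv,
                              detail = TRUE)
  pTrain <- predictProbability(ensemble, Xcand)
  mTrain <- computeMetrics(ytr, pTrain)

  cvSd <- apply(cvRes$perFold, 2, stats::sd)
  cvRow <- data.frame(acc = cvRes$fitness["acc"],
                      spec = mean(cvRes$perFold[, "spec"]),
                      sens = cvRes$fitness["rec"],
                      f1 = cvRes$fitness["f1"],
                      f2 = cvRes$fitness["f2"],
                      auc = cvRes$fitness["auc"], row.names = NULL)
  rows <- list(
    data.frame(set = "training", .metricsRow(mTrain), sd = NA_real_),
    data.frame(set = "cv", cvRow, sd = mean(cvSd))
  )

  if (length(teIdx)) {
    dtTest <- computeDescriptors(smiles[teIdx], ids = ids[teIdx])
    XteAll <- descValues(knnImpute(.restrictFeatures(dtTest,
                                                     params@keptFeatures),
                                   k = params@knnK))
    Xte <- descValues(applyMinmax(.DescriptorTable(XteAll), params))
    pTest <- predictProbability(ensemble, Xte)
    mTest <- computeMetrics(y[teIdx], pTest)
    rows <- c(rows, list(data.frame(set = "test", .metricsRow(mTest),
                                    sd = NA_real_)))
  }
  tab <- do.call(rbind, rows)
  attr(tab, "cvSd") <- cvSd
  tab
}

.restrictFeatures <- function(dt, feats) {
  .DescriptorTable(dt@values[, intersect(feats, colnames(dt@values)),
                             drop = FALSE])
}

.metricsRow <- function(m) {
  data.frame(acc = m$acc, spec = m$spec, sens = m$sens, f1 = m$f1,
             f2 = m$f2, auc = m$auc)
}

.specOf <- function(model) {
  list(features = model@features, classifier = model@classifier,
       C = model@hyper$C, gamma = model@hyper$gamma,
       ntrees = model@hyper$ntrees, feasible = TRUE)
}

#' Predict query molecules with a trained bundle
#'
#' Standardizes each input (failures are isolated per molecule), computes
#' descriptors restricted to the bundle's feature space, applies the
#' frozen normalization, checks the applicability domain and predicts
#' with the ensemble. Molecules outside the domain are still predicted
#' but flagged.
#'
#' @param bundle an \code{"umamiBundle"} (or a bundle directory path).
#' @param inputs character vector of molecule strings, or a file path
#'   (\code{.smi} / FASTA / one-per-line text).
#' @param format \code{"smiles"}, \code{"fasta"} or \code{"inchi"}.
#' @param adThreshold optional override of the stored AD threshold.
#' @return data.frame: \code{id}, \code{input}, \code{canonical_smiles},
#'   \code{in_domain}, \code{ad_score}, \code{prediction},
#'   \code{probability_umami}, \code{message}.
#' @export
predictUmami <- function(bundle, inputs,
                         format = c("smiles", "fasta", "inchi"),
                         adThreshold = NULL) {
  format <- match.arg(format)
  bundle <- .asBundle(bundle)
  notation <- c(smiles = "smiles", fasta = "fasta_peptide",
                inchi = "inchi")[format]
  items <- .readQueryInputs(inputs, format)
  ad <- bundle$ad
  if (!is.null(adThreshold)) ad@threshold <- adThreshold

  out <- vector("list", nrow(items))
  for (i in seq_len(nrow(items))) {
    rec <- standardizeMolecule(items$input[i], notation = notation,
                               id = items$id[i])
    if (rec$excluded) {
      out[[i]] <- data.frame(
        id = rec$id, input = rec$source_text, canonical_smiles = "",
        in_domain = NA, ad_score = NA_real_,
        prediction = NA_character_, probability_umami = NA_real_,
        message = rec$message, stringsAsFactors = FALSE)
      next
    }
    chk <- adCheck(rec$canonical_smiles, ad)
    p <- .predictOneSmiles(bundle, rec$canonical_smiles, rec$id)
    out[[i]] <- data.frame(
      id = rec$id, input = rec$source_text,
      canonical_smiles = rec$canonical_smiles,
      in_domain = chk$inDomain, ad_score = chk$score,
      prediction = if (p > 0.5) "Umami" else "Non-umami",
      probability_umami = p, message = rec$message,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.predictOneSmiles <- function(bundle, smiles, id) {
  dt <- computeDescriptors(smiles, ids = id)
  dt <- .restrictFeatures(dt, bundle$params@keptFeatures)
  X <- descValues(applyMinmax(dt, bundle$params))
  # single query rows cannot be kNN-imputed against themselves; missing
  # cells fall back to the normalized training midpoint
  X[is.na(X)] <- 0.5
  unname(predictProbability(bundle$ensemble, X))
}

.readQueryInputs <- function(inputs, format) {
  if (length(inputs) == 1L && file.exists(inputs)) {
    if (format == "fasta") {
      df <- .readFastaPair(inputs)
      return(data.frame(id = df$id, input = df$input,
                        stringsAsFactors = FALSE))
    }
    df <- .readSmi(inputs, labels = NULL)
    return(data.frame(id = df$id, input = df$input,
                      stringsAsFactors = FALSE))
  }
  ids <- names(inputs)
  if (is.null(ids)) ids <- paste0("query", seq_along(inputs))
  data.frame(id = ids, input = unname(inputs), stringsAsFactors = FALSE)
}

#' Screen a compound database through the AD gate
#'
#' Two-stage protocol: the applicability-domain filter runs first and the
#' prediction is performed only on the inside-domain portion; the summary
#' reports the fractions at both stages.
#'
#' @inheritParams predictUmami
#' @return list: \code{insideAD} (report rows inside the domain, with
#'   predictions), \code{outsideAD} (rows outside, no prediction),
#'   \code{summary} (counts: total, parsed, inside, predictedUmami).
#' @export
screenDatabase <- function(bundle, inputs,
                           format = c("smiles", "fasta", "inchi"),
                           adThreshold = NULL) {
  format <- match.arg(format)
  bundle <- .asBundle(bundle)
  notation <- c(smiles = "smiles", fasta = "fasta_peptide",
                inchi = "inchi")[format]
  items <- .readQueryInputs(inputs, format)
  ad <- bundle$ad
  if (!is.null(adThreshold)) ad@threshold <- adThreshold

  inside <- list(); outside <- list()
  nParsed <- 0L
  for (i in seq_len(nrow(items))) {
    rec <- standardizeMolecule(items$input[i], notation = notation,
                               id = items$id[i])
    if (rec$excluded) next
    nParsed <- nParsed + 1L
    chk <- adCheck(rec$canonical_smiles, ad)
    row <- data.frame(id = rec$id, canonical_smiles = rec$canonical_smiles,
                      ad_score = chk$score, stringsAsFactors = FALSE)
    if (chk$inDomain) {
      p <- .predictOneSmiles(bundle, rec$canonical_smiles, rec$id)
      row$prediction <- if (p > 0.5) "Umami" else "Non-umami"
      row$probability_umami <- p
      inside[[length(inside) + 1L]] <- row
    } else {
      outside[[length(outside) + 1L]] <- row
    }
  }
  insideDf <- if (length(inside)) do.call(rbind, inside) else NULL
  outsideDf <- if (length(outside)) do.call(rbind, outside) else NULL
  nUmami <- if (is.null(insideDf)) 0L else
    sum(insideDf$prediction == "Umami")
  list(insideAD = insideDf, outsideAD = outsideDf,
       summary = c(total = nrow(items), parsed = nParsed,
                   insideAD = if (is.null(insideDf)) 0L else
                     nrow(insideDf),
                   predictedUmami = nUmami))
}

## ---- bundle serialization (plain text) ----

#' Write / read a trained model bundle
#'
#' The bundle directory contains only plain-text artifacts: preprocessing
#' parameters (key-value), the preprocessed training matrix and labels
#' (CSV), member model specifications (key-value), AD fingerprints
#' (hex-encoded), the metrics table and an ensemble manifest. On read the
#' member classifiers are refitted deterministically from the stored
#' training matrix under the stored seeds.
#'
#' @param bundle an \code{"umamiBundle"}.
#' @param dir bundle directory.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- bundle$params
  writeLines(c(
    sprintf("maxMissingFrac=%.17g", p@maxMissingFrac),
    sprintf("knnK=%d", p@knnK),
    sprintf("seed=%d", bundle$config$seed),
    sprintf("features=%s", paste(p@keptFeatures, collapse = ",")),
    sprintf("min=%s", paste(sprintf("%.17g", p@featureMin),
                            collapse = ",")),
    sprintf("max=%s", paste(sprintf("%.17g", p@featureMax),
                            collapse = ","))),
    file.path(dir, "preprocess.txt"))

  # full-precision text so the refit-on-load reproduces bit-identical
  # classifiers
  tm <- data.frame(label = bundle$trainY,
                   apply(bundle$trainX, 2, function(col)
                     sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tm, file.path(dir, "train_matrix.csv"),
                   row.names = FALSE)

  for (side in c("A", "B")) {
    m <- slot(bundle$ensemble, paste0("member", side))
    writeLines(c(
      sprintf("classifier=%s", m@classifier),
      sprintf("C=%.17g", m@hyper$C %||% NA),
      sprintf("gamma=%.17g", m@hyper$gamma %||% NA),
      sprintf("ntrees=%d", as.integer(m@hyper$ntrees %||% 0)),
      sprintf("seed=%d", m@seed),
      sprintf("tag=%s", m@tag),
      sprintf("features=%s", paste(m@features, collapse = ","))),
      file.path(dir, sprintf("model_%s.txt", tolower(side))))
  }
  writeLines(sprintf("ensemble=%s", bundle$ensemble@tag),
             file.path(dir, "manifest.txt"))
  writeADModel(bundle$ad, file.path(dir, "ad.txt"))
  utils::write.csv(bundle$metricsTable, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$comparison))
    utils::write.csv(bundle$comparison,
                     file.path(dir, "ensemble_comparison.csv"),
                     row.names = FALSE)
  writeVolcanoCsv(bundle$stats, file.path(dir, "feature_stats.csv"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  kv <- function(path) {
    lines <- readLines(path)
    keys <- sub("=.*$", "", lines)
    vals <- sub("^[^=]*=", "", lines)
    stats::setNames(as.list(vals), keys)
  }
  pp <- kv(file.path(dir, "preprocess.txt"))
  feats <- strsplit(pp$features, ",", fixed = TRUE)[[1]]
  params <- new("PreprocessParams",
                maxMissingFrac = as.numeric(pp$maxMissingFrac),
                knnK = as.integer(pp$knnK), keptFeatures = feats,
                featureMin = stats::setNames(
                  as.numeric(strsplit(pp$min, ",")[[1]]), feats),
                featureMax = stats::setNames(
                  as.numeric(strsplit(pp$max, ",")[[1]]), feats),
                fitted = TRUE, seed = as.integer(pp$seed))

  tm <- utils::read.csv(file.path(dir, "train_matrix.csv"),
                        check.names = FALSE)
  trainY <- as.integer(tm$label)
  trainX <- as.matrix(tm[, -1, drop = FALSE])

  readMember <- function(side) {
    mv <- kv(file.path(dir, sprintf("model_%s.txt", side)))
    spec <- list(features = strsplit(mv$features, ",")[[1]],
                 classifier = mv$classifier, C = as.numeric(mv$C),
                 gamma = as.numeric(mv$gamma),
                 ntrees = as.integer(mv$ntrees), feasible = TRUE)
    trainFinal(spec, trainX, trainY, seed = as.integer(mv$seed),
               tag = mv$tag)
  }
  ensemble <- makeEnsemble(readMember("a"), readMember("b"),
                           tag = kv(file.path(dir,
                                              "manifest.txt"))$ensemble)
  bundle <- list(params = params, ensemble = ensemble,
                 ad = readADModel(file.path(dir, "ad.txt")),
                 archive = NULL,
                 stats = utils::read.csv(file.path(dir,
                                                   "feature_stats.csv")),
                 metricsTable = utils::read.csv(file.path(dir,
                                                          "metrics.csv")),
                 trainX = trainX, trainY = trainY,
                 config = list(seed = as.integer(pp$seed)),
                 weights = goalWeights(), comparison = NULL)
  class(bundle) <- "umamiBundle"
  bundle
}

.asBundle <- function(x) {
  if (inherits(x, "umamiBundle")) return(x)
  if (is.character(x) && dir.exists(x)) return(readBundle(x))
  stop("expected an umamiBundle or a bundle directory path")
}

#' @export
print.umamiBundle <- function(x, ...) {
  cat("umamiBundle\n")
  cat("  ensemble:", x$ensemble@tag, "\n")
  cat("  features:", paste(modelFeatures(x$ensemble), collapse = ", "),
      "\n")
  cat("  training samples:", length(x$trainY), "\n")
  print(x$metricsTable, digits = 3)
  invisible(x)
}
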