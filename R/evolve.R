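# Weighted multi-objective Pareto evolutionary search over feature
# subsets, selector combinations, classifier family and hyperparameters,
# evaluated by stratified 10-fold cross-validation with per-fold minority
# oversampling.
#
# Chromosome encoding (all genes real in [0, 1]):
#   [1..4]    enable bits for {wilcoxon, kbest, mrmr, jmim} (> 0.5 = on)
#   [5..8]    top-k genes per method, mapped linearly to [5, min(100, F)]
#   [9..8+F]  feature inclusion genes over the candidate pool
#   [9+F]     classifier gene (<= 0.5 SVM, > 0.5 random forest)
#   [10+F]    C gene, log-uniform in [1e-2, 1e3]
#   [11+F]    gamma gene, log-uniform in [1e-4, 1e1]
#   [12+F]    ntrees gene, linear in [10, 500]
# A feature is selected iff its gene exceeds 0.5 AND it belongs to the
# union of the enabled selectors' top-k prefixes. Chromosomes decoding to
# an empty feature set are infeasible and receive worst-case fitness.

#' Goal weights of the multi-objective search
#'
#' The scalarization weights applied to the fitness components: feature
#' minimization 5, accuracy 10, F1 5, F2 1, precision 1, recall 10,
#' ROC-AUC 1, model-size minimization 1.
#'
#' @param featMin,acc,f1,f2,prc,rec,auc,modelMin non-negative weights.
#' @return named numeric vector of the eight weights.
#' @export
goalWeights <- function(featMin = 5, acc = 10, f1 = 5, f2 = 1, prc = 1,
                        rec = 10, auc = 1, modelMin = 1) {
  w <- c(featMin = featMin, acc = acc, f1 = f1, f2 = f2, prc = prc,
         rec = rec, auc = auc, modelMin = modelMin)
  stopifnot(all(w >= 0))
  w
}

#' Evolutionary optimizer configuration
#'
#' Defaults mirror the reference protocol: population 50, at most 100
#' generations, two-point crossover probability 0.9, per-gene mutation
#' probability 0.01, arithmetic crossover off, stratified 10-fold CV,
#' 5 repeated runs.
#'
#' @param population,generations,pCrossover,pMutation,pArithmetic,nFolds,nRuns,seed
#'   configuration fields.
#' @param kRange top-k gene range for the selector prefixes.
#' @param tournamentSize selection tournament size.
#' @return named list of class \code{"optimizerConfig"}.
#' @export
optimizerConfig <- function(population = 50L, generations = 100L,
                            pCrossover = 0.9, pMutation = 0.01,
                            pArithmetic = 0, nFolds = 10L, nRuns = 5L,
                            seed = 1L, kRange = c(5L, 100L),
                            tournamentSize = 2L) {
  cfg <- list(population = as.integer(population),
              generations = as.integer(generations),
              pCrossover = pCrossover, pMutation = pMutation,
              pArithmetic = pArithmetic, nFolds = as.integer(nFolds),
              nRuns = as.integer(nRuns), seed = as.integer(seed),
              kRange = as.integer(kRange),
              tournamentSize = as.integer(tournamentSize))
  if (cfg$population < 2L) stop("population must be at least 2")
  if (cfg$generations < 1L) stop("need at least one generation")
  class(cfg) <- "optimizerConfig"
  cfg
}

.SELECTOR_NAMES <- c("wilcoxon", "kbest", "mrmr", "jmim")

# Precompute the four selector orderings once per dataset.
.rankAllSelectors <- function(X, y, kMax, bins = 10L) {
  list(
    wilcoxon = wilcoxonRank(X, y)$feature,
    kbest = kbestRank(X, y)$feature,
    mrmr = mrmrSelect(X, y, k = kMax, bins = bins)$feature,
    jmim = jmimSelect(X, y, k = kMax, bins = bins)$feature
  )
}

.chromLength <- function(nFeatures) nFeatures + 12L

#' Decode a chromosome into a model specification
#'
#' Builds the candidate pool as the union of the enabled selectors' top-k
#' prefixes, keeps pool features whose inclusion gene exceeds 0.5, and
#' maps the hyperparameter genes to classifier settings. An empty decoded
#' feature set yields \code{feasible = FALSE} rather than an error.
#'
#' @param chrom numeric gene vector (see package vignette for layout).
#' @param ranked list of best-first feature orderings per selector, as
#'   produced internally from the four selection methods.
#' @param featureNames candidate feature names (defines gene order).
#' @param kRange integer length-2 top-k gene range.
#' @return list: \code{features}, \code{classifier}, \code{C},
#'   \code{gamma}, \code{ntrees}, \code{selectors}, \code{feasible}.
#' @export
decodeChromosome <- function(chrom, ranked, featureNames,
                             kRange = c(5L, 100L)) {
  nF <- length(featureNames)
  stopifnot(length(chrom) == .chromLength(nF))
  mask <- chrom[1:4] > 0.5
  if (!any(mask)) mask[which.max(chrom[1:4])] <- TRUE  # at least one method
  kHi <- min(kRange[2], nF)
  kLo <- min(kRange[1], nF)
  ks <- round(kLo + chrom[5:8] * (kHi - kLo))
  pool <- character(0)
  for (m in which(mask)) {
    pool <- union(pool, utils::head(ranked[[.SELECTOR_NAMES[m]]], ks[m]))
  }
  genes <- chrom[9:(8 + nF)]
  names(genes) <- featureNames
  feats <- featureNames[featureNames %in% pool & genes > 0.5]
  list(
    features = feats,
    classifier = if (chrom[9 + nF] <= 0.5) "svm" else "rf",
    C = 10^(-2 + chrom[10 + nF] * 5),
    gamma = 10^(-4 + chrom[11 + nF] * 5),
    ntrees = as.integer(round(10 + chrom[12 + nF] * 490)),
    selectors = .SELECTOR_NAMES[mask],
    feasible = length(feats) > 0L
  )
}

.FITNESS_NAMES <- c("acc", "prc", "rec", "f1", "f2", "auc",
                    "featFrac", "modelSizeFrac")

.worstFitness <- function() {
  stats::setNames(c(0, 0, 0, 0, 0, 0, 1, 1), .FITNESS_NAMES)
}

# Gain-oriented view: minimization components flipped to 1 - frac.
.fitnessGains <- function(fit) {
  g <- fit
  g["featFrac"] <- 1 - fit["featFrac"]
  g["modelSizeFrac"] <- 1 - fit["modelSizeFrac"]
  names(g) <- c("acc", "prc", "rec", "f1", "f2", "auc", "featMin",
                "modelMin")
  g
}

#' Scalarized fitness
#'
#' Weighted sum of the fitness components with the two minimization goals
#' entered as \code{1 - fraction}; used to rank within Pareto fronts and
#' to pick the final model. A perfect model with zero features and zero
#' size scores the sum of the weights (24 under the defaults).
#'
#' @param fit named fitness vector (components \code{acc}, \code{prc},
#'   \code{rec}, \code{f1}, \code{f2}, \code{auc}, \code{featFrac},
#'   \code{modelSizeFrac}).
#' @param weights from \code{\link{goalWeights}}.
#' @return numeric scalar.
#' @export
scalarize <- function(fit, weights = goalWeights()) {
  g <- .fitnessGains(fit)
  perf <- c("acc", "prc", "rec", "f1", "f2", "auc")
  unname(sum(weights[perf] * g[perf]) +
           weights["featMin"] * g["featMin"] +
           weights["modelMin"] * g["modelMin"])
}

#' Non-dominated sorting into Pareto fronts
#'
#' Peels successive non-dominated sets from a list of fitness vectors in
#' maximization orientation (vector a dominates b when a >= b everywhere
#' and a > b somewhere).
#'
#' @param fitnessList list of equal-length numeric vectors, or a matrix
#'   with one row per solution.
#' @return list of integer index vectors, front 0 first.
#' @export
paretoRank <- function(fitnessList) {
  M <- if (is.matrix(fitnessList)) fitnessList else
    do.call(rbind, fitnessList)
  n <- nrow(M)
  if (n == 0L) stop("empty fitness list")
  dominates <- function(a, b) all(M[a, ] >= M[b, ]) && any(M[a, ] > M[b, ])
  domCount <- integer(n)
  dominated <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) dominated[[i]] <- c(dominated[[i]], j)
      if (dominates(j, i)) domCount[i] <- domCount[i] + 1L
    }
  }
  fronts <- list()
  assigned <- rep(FALSE, n)
  current <- which(domCount == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    assigned[current] <- TRUE
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated[[i]]) {
        domCount[j] <- domCount[j] - 1L
        if (domCount[j] == 0L && !assigned[j]) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

# Per-sample front index (0-based like the front list order).
.frontIndex <- function(fronts, n) {
  fi <- integer(n)
  for (k in seq_along(fronts)) fi[fronts[[k]]] <- k - 1L
  fi
}

#' Cross-validated fitness of a decoded model
#'
#' Stratified k-fold cross-validation in which the training folds are
#' minority-oversampled (the evaluation fold never is), the decoded
#' classifier is fitted on the selected features, and the held-out fold is
#' scored. Components are fold means; the model-size fraction is the mean
#' support-vector count over training rows (SVM) or the tree count
#' normalized to its gene range (RF). Infeasible specs score worst-case.
#'
#' @param spec decoded model list from \code{\link{decodeChromosome}}.
#' @param X preprocessed training matrix.
#' @param y binary labels.
#' @param cv fold container from \code{\link{makeCvPlan}}.
#' @param nCandidates size of the candidate feature pool (denominator of
#'   the feature fraction); defaults to \code{ncol(X)}.
#' @return named fitness vector.
#' @export
evaluateFitness <- function(spec, X, y, cv, nCandidates = ncol(X)) {
  if (!isTRUE(spec$feasible)) return(.worstFitness())
  feats <- spec$features
  comp <- matrix(NA_real_, length(cv$folds), 7)
  sizeFracs <- numeric(length(cv$folds))
  for (f in seq_along(cv$folds)) {
    testIdx <- cv$folds[[f]]
    trainIdx <- cv$trainIndex[[f]]   # oversampled already
    fitRes <- tryCatch(
      .fitClassifier(spec, X[trainIdx, feats, drop = FALSE], y[trainIdx],
                     seed = cv$foldSeeds[f]),
      error = function(e) NULL)
    if (is.null(fitRes)) {
      comp[f, ] <- c(0, 0, 0, 0, 0, 0, 0)
      sizeFracs[f] <- 1
      next
    }
    p <- .predictProb(fitRes, X[testIdx, feats, drop = FALSE])
    m <- computeMetrics(y[testIdx], p)
    comp[f, ] <- c(m$acc, m$prc, m$rec, m$f1, m$f2,
                   if (is.na(m$auc)) 0.5 else m$auc, 0)
    sizeFracs[f] <- min(1, fitRes$sizeFrac)
  }
  means <- colMeans(comp)
  stats::setNames(
    c(means[1:6], length(feats) / nCandidates, mean(sizeFracs)),
    .FITNESS_NAMES)
}

#' Build the cross-validation plan
#'
#' Fixes the stratified fold assignment and the per-fold oversampled
#' training index once per search, so that every chromosome is evaluated
#' on identical folds.
#'
#' @param y binary labels.
#' @param nFolds folds, default 10.
#' @param seed integer seed.
#' @return list: \code{folds} (test indices per fold), \code{trainIndex}
#'   (oversampled training indices per fold), \code{foldSeeds}.
#' @export
makeCvPlan <- function(y, nFolds = 10L, seed = 1L) {
  fold <- stratifiedKfold(y, nFolds = nFolds, seed = seed)
  folds <- lapply(seq_len(nFolds), function(f) which(fold == f))
  trainIndex <- vector("list", nFolds)
  foldSeeds <- integer(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- which(fold != f)
    os <- randomOversample(matrix(0, length(tr), 1), y[tr],
                           seed = .childSeed(seed, "oversample", f))
    trainIndex[[f]] <- tr[os$index]
    foldSeeds[f] <- .childSeed(seed, "fold", f)
  }
  list(folds = folds, trainIndex = trainIndex, foldSeeds = foldSeeds)
}

#' Evolutionary search over features, classifier and hyperparameters
#'
#' Runs the seeded genetic search: tournament selection on (Pareto front
#' rank, scalarized score), two-point crossover, per-gene mutation, an
#' elitist all-time archive of non-dominated solutions, and a convergence
#' log of population-average versus best scalarized score per generation.
#'
#' @param X preprocessed, prioritized training matrix (columns are the
#'   candidate features).
#' @param y binary labels.
#' @param config an \code{\link{optimizerConfig}}.
#' @param weights \code{\link{goalWeights}}.
#' @param bins MI discretization bins for the selector precomputation.
#' @return list of class \code{"paretoArchive"}: \code{members} (each with
#'   \code{chrom}, \code{spec}, \code{fitness}, \code{scalar}),
#'   \code{ranked} selector orderings, \code{cv} plan,
#'   \code{convergence} data.frame, \code{config}, \code{weights}.
#' @export
evolveModels <- function(X, y, config = optimizerConfig(),
                         weights = goalWeights(), bins = 10L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  nF <- ncol(X)
  L <- .chromLength(nF)
  ranked <- .rankAllSelectors(X, y, kMax = min(config$kRange[2], nF),
                              bins = bins)
  cv <- makeCvPlan(y, nFolds = config$nFolds, seed = config$seed)
  cache <- new.env(parent = emptyenv())

  evalChrom <- function(chrom) {
    spec <- decodeChromosome(chrom, ranked, colnames(X), config$kRange)
    key <- paste(spec$classifier, signif(spec$C, 6), signif(spec$gamma, 6),
                 spec$ntrees, paste(spec$features, collapse = ","),
                 sep = "|")
    if (!is.null(cache[[key]])) return(list(spec = spec,
                                            fitness = cache[[key]]))
    fit <- evaluateFitness(spec, X, y, cv, nCandidates = nF)
    cache[[key]] <- fit
    list(spec = spec, fitness = fit)
  }

  pop <- .withSeed(.childSeed(config$seed, "init"),
    lapply(seq_len(config$population), function(i) stats::runif(L)))
  evals <- lapply(pop, evalChrom)

  archive <- list()
  updateArchive <- function(pop, evals) {
    all <- c(archive, lapply(seq_along(pop), function(i)
      list(chrom = pop[[i]], spec = evals[[i]]$spec,
           fitness = evals[[i]]$fitness)))
    keys <- vapply(all, function(m)
      paste(signif(m$fitness, 10), collapse = ","), character(1))
    all <- all[!duplicated(keys)]
    G <- do.call(rbind, lapply(all, function(m) .fitnessGains(m$fitness)))
    fronts <- paretoRank(G)
    archive <<- all[fronts[[1]]]
  }
  updateArchive(pop, evals)

  conv <- data.frame(generation = integer(0), meanScalar = numeric(0),
                     bestScalar = numeric(0))

  for (gen in seq_len(config$generations)) {
    G <- do.call(rbind, lapply(evals, function(e) .fitnessGains(e$fitness)))
    fronts <- paretoRank(G)
    fi <- .frontIndex(fronts, length(pop))
    sc <- vapply(evals, function(e) scalarize(e$fitness, weights),
                 numeric(1))
    conv <- rbind(conv, data.frame(generation = gen,
                                   meanScalar = mean(sc),
                                   bestScalar = max(sc)))

    newPop <- .withSeed(.childSeed(config$seed, "gen", gen), {
      select1 <- function() {
        cand <- sample.int(length(pop), config$tournamentSize,
                           replace = TRUE)
        best <- cand[order(fi[cand], -sc[cand])][1]
        best
      }
      offspring <- vector("list", config$population)
      # elitism: carry the best scalarized individual unchanged
      eliteIdx <- order(fi, -sc)[1]
      offspring[[1]] <- pop[[eliteIdx]]
      i <- 2L
      while (i <= config$population) {
        p1 <- pop[[select1()]]; p2 <- pop[[select1()]]
        if (stats::runif(1) < config$pCrossover) {
          cut <- sort(sample.int(L - 1L, 2L))
          mid <- seq(cut[1] + 1L, cut[2])
          tmp <- p1[mid]; p1[mid] <- p2[mid]; p2[mid] <- tmp
        } else if (config$pArithmetic > 0 &&
                   stats::runif(1) < config$pArithmetic) {
          a <- stats::runif(1)
          c1 <- a * p1 + (1 - a) * p2
          p2 <- (1 - a) * p1 + a * p2
          p1 <- c1
        }
        for (ch in list(p1, p2)) {
          if (i > config$population) break
          mut <- stats::runif(L) < config$pMutation
          ch[mut] <- stats::runif(sum(mut))
          offspring[[i]] <- ch
          i <- i + 1L
        }
      }
      offspring
    })
    pop <- newPop
    evals <- lapply(pop, evalChrom)
    updateArchive(pop, evals)
  }

  members <- lapply(archive, function(m) {
    m$scalar <- scalarize(m$fitness, weights)
    m
  })
  ord <- order(-vapply(members, `[[`, numeric(1), "scalar"))
  out <- list(members = members[ord], ranked = ranked, cv = cv,
              convergence = conv, config = config, weights = weights)
  class(out) <- "paretoArchive"
  out
}

#' @export
print.paretoArchive <- function(x, ...) {
  cat("Pareto archive:", length(x$members), "non-dominated models\n")
  top <- utils::head(x$members, 5)
  for (m in top) {
    cat(sprintf("  [%s] %d features, CV acc %.3f, scalar %.2f\n",
                m$spec$classifier, length(m$spec$features),
                m$fitness["acc"], m$scalar))
  }
  invisible(x)
}

#' Repeated evolutionary runs
#'
#' Runs \code{\link{evolveModels}} \code{nRuns} times under derived seeds
#' and reports the per-run best models plus mean and standard deviation of
#' their cross-validated metrics.
#'
#' @inheritParams evolveModels
#' @return list: \code{runs} (archives), \code{best} (per-run top member),
#'   \code{summary} (mean/sd data.frame over runs).
#' @export
evolveRepeated <- function(X, y, config = optimizerConfig(),
                           weights = goalWeights(), bins = 10L) {
  runs <- vector("list", config$nRuns)
  for (r in seq_len(config$nRuns)) {
    cfg <- config
    cfg$seed <- .childSeed(config$seed, "run", r)
    runs[[r]] <- evolveModels(X, y, cfg, weights, bins = bins)
  }
  best <- lapply(runs, function(a) a$members[[1]])
  M <- do.call(rbind, lapply(best, function(m) m$fitness))
  list(runs = runs, best = best,
       summary = data.frame(metric = colnames(M),
                            mean = colMeans(M),
                            sd = apply(M, 2, stats::sd),
                            row.names = NULL))
}

#' Fit the final model for a decoded specification
#'
#' Fits the classifier on the minority-oversampled full training split
#' restricted to the selected features.
#'
#' @param spec decoded model list (\code{\link{decodeChromosome}}).
#' @param X preprocessed training matrix.
#' @param y binary labels.
#' @param seed integer seed (oversampling and RF).
#' @param tag provenance tag stored on the model.
#' @return An \linkS4class{UmamiModel}.
#' @export
trainFinal <- function(spec, X, y, seed = 1L, tag = "") {
  if (!isTRUE(spec$feasible)) stop("cannot train an infeasible spec")
  os <- randomOversample(X[, spec$features, drop = FALSE], y,
                         seed = .childSeed(seed, "final-oversample"))
  fitRes <- .fitClassifier(spec, os$X, os$y, seed = .childSeed(seed, "fit"))
  new("UmamiModel", features = spec$features,
      classifier = spec$classifier,
      hyper = list(C = spec$C, gamma = spec$gamma, ntrees = spec$ntrees),
      fit = fitRes$fit, calibration = fitRes$calibration,
      seed = as.integer(seed), tag = tag)
}
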