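# Classification metrics, Pareto machinery and the evolutionary search.

test_that("metrics match hand evaluation", {
  m <- computeMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$acc, 1); expect_equal(m$auc, 1)
  expect_equal(m$f1, 1); expect_equal(m$f2, 1)

  # inverted scores
  mi <- computeMetrics(c(1, 0), c(0.4, 0.6))
  expect_equal(mi$acc, 0); expect_equal(mi$auc, 0)

  # F2 at precision 0.5, recall 1: 5*0.5*1/(4*0.5+1) = 0.8333...
  # realized by 1 TP, 1 FP, 0 FN
  mf <- computeMetrics(c(1, 0, 0), c(0.9, 0.8, 0.1))
  expect_equal(mf$prc, 0.5); expect_equal(mf$rec, 1)
  expect_equal(mf$f2, 5 * 0.5 * 1 / (4 * 0.5 + 1), tolerance = 1e-12)
  expect_equal(round(mf$f2, 4), 0.8333)

  # single-class truth: AUC undefined
  expect_true(is.na(computeMetrics(c(1, 1), c(0.6, 0.7))$auc))
  expect_true(m$TP + m$FP + m$TN + m$FN == 4)
})

test_that("rank AUC equals the reference concordance with ties", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (rep in 1:10) {
    y <- sample(c(0L, 1L), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    p <- round(runif(30), 1)  # coarse grid forces ties
    ref <- suppressMessages(as.numeric(pROC::auc(y, p,
                                                 direction = "<")))
    expect_equal(aucRank(y, p), ref, tolerance = 1e-12)
  }
})

test_that("Pareto fronts agree with the brute-force dominance oracle", {
  expect_identical(paretoRank(list(c(1, 1), c(0.5, 0.5)))[[1]], 1L)
  both <- paretoRank(list(c(1, 0), c(0, 1)))
  expect_identical(sort(both[[1]]), c(1L, 2L))

  bruteFronts <- function(M) {
    idx <- seq_len(nrow(M)); fronts <- list()
    while (length(idx)) {
      nd <- idx[vapply(idx, function(i) !any(vapply(idx, function(j)
        j != i && all(M[j, ] >= M[i, ]) && any(M[j, ] > M[i, ]),
        logical(1))), logical(1))]
      fronts[[length(fronts) + 1L]] <- sort(nd)
      idx <- setdiff(idx, nd)
    }
    fronts
  }
  set.seed(6)
  for (rep in 1:5) {
    M <- matrix(runif(150), 50, 3)
    got <- lapply(paretoRank(M), sort)
    expect_identical(got, bruteFronts(M))
  }
})

test_that("scalarization follows the stated goal weights", {
  w <- goalWeights()
  perfect <- setNames(c(1, 1, 1, 1, 1, 1, 0, 0),
                      UmamiQSAR:::.FITNESS_NAMES)
  expect_equal(scalarize(perfect, w), sum(w))
  worst <- setNames(c(0, 0, 0, 0, 0, 0, 1, 1),
                    UmamiQSAR:::.FITNESS_NAMES)
  expect_equal(scalarize(worst, w), 0)
  # +0.1 accuracy moves the score by 0.1 * w_acc = 1.0
  bumped <- perfect; bumped["acc"] <- 0.9
  expect_equal(scalarize(perfect, w) - scalarize(bumped, w), 1.0)
  expect_equal(unname(w), c(5, 10, 5, 1, 1, 10, 1, 1))
})

test_that("chromosome decoding honours pool, genes and infeasibility", {
  feats <- paste0("f", 1:6)
  ranked <- list(wilcoxon = feats, kbest = rev(feats),
                 mrmr = feats, jmim = feats)
  nF <- 6L
  chrom <- rep(0.9, UmamiQSAR:::.chromLength(nF))
  chrom[1:4] <- c(0.9, 0.1, 0.1, 0.1)     # only wilcoxon enabled
  chrom[5] <- 0                           # k at its lower bound
  spec <- decodeChromosome(chrom, ranked, feats, kRange = c(3L, 100L))
  expect_identical(spec$features, feats[1:3])
  expect_identical(spec$selectors, "wilcoxon")
  expect_true(spec$feasible)

  # all feature genes low: infeasible, not an error
  chrom2 <- chrom; chrom2[9:(8 + nF)] <- 0.1
  expect_false(decodeChromosome(chrom2, ranked, feats,
                                kRange = c(3L, 100L))$feasible)

  # overlapping selectors merge without duplicates
  chrom3 <- chrom; chrom3[1:4] <- 0.9; chrom3[5:8] <- 0
  spec3 <- decodeChromosome(chrom3, ranked, feats, kRange = c(3L, 100L))
  expect_identical(anyDuplicated(spec3$features), 0L)
  expect_setequal(spec3$selectors,
                  c("wilcoxon", "kbest", "mrmr", "jmim"))

  # hyperparameter gene mapping spans the documented ranges
  lo <- chrom; lo[(9 + nF):(12 + nF)] <- 0
  hi <- chrom; hi[(9 + nF):(12 + nF)] <- 1
  sLo <- decodeChromosome(lo, ranked, feats, c(3L, 100L))
  sHi <- decodeChromosome(hi, ranked, feats, c(3L, 100L))
  expect_equal(sLo$C, 1e-2); expect_equal(sHi$C, 1e3)
  expect_equal(sLo$gamma, 1e-4); expect_equal(sHi$gamma, 1e1)
  expect_identical(sLo$ntrees, 10L); expect_identical(sHi$ntrees, 500L)
  expect_identical(sLo$classifier, "svm")
  expect_identical(sHi$classifier, "rf")
})

test_that("fitness evaluation is separable-perfect, null-random, seeded", {
  set.seed(2)
  n <- 60
  X <- cbind(sig = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             noise = rnorm(n))
  colnames(X) <- c("sig", "noise")
  y <- rep(c(1L, 0L), each = n / 2)
  cv <- makeCvPlan(y, nFolds = 5, seed = 10)
  spec <- list(features = "sig", classifier = "svm", C = 10, gamma = 0.5,
               ntrees = 100L, feasible = TRUE)
  fit <- evaluateFitness(spec, X, y, cv)
  expect_equal(unname(fit["acc"]), 1)
  expect_equal(unname(fit["auc"]), 1)

  # permuted labels: AUC hovers around chance
  aucs <- vapply(1:5, function(s) {
    yp <- UmamiQSAR:::.withSeed(s, sample(y))
    cvp <- makeCvPlan(yp, nFolds = 5, seed = s)
    unname(evaluateFitness(spec, X, yp, cvp)["auc"])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  # determinism contract
  expect_identical(evaluateFitness(spec, X, y, cv),
                   evaluateFitness(spec, X, y, cv))

  # infeasible chromosome scores worst-case
  bad <- list(features = character(0), feasible = FALSE)
  expect_equal(unname(evaluateFitness(bad, X, y, cv)),
               c(0, 0, 0, 0, 0, 0, 1, 1))
})

test_that("the evolutionary search runs, converges and reproduces", {
  pd <- makePlantedDataset(nPos = 25, nNeg = 25, nFeatures = 12,
                           nInformative = 3, effectSize = 2.5, rho = 0.2,
                           seed = 33)
  cfg <- optimizerConfig(population = 8, generations = 4, nFolds = 5,
                         nRuns = 1, seed = 5)
  arc <- evolveModels(pd$X, pd$y, cfg)
  expect_s3_class(arc, "paretoArchive")
  expect_gt(length(arc$members), 0)
  expect_identical(nrow(arc$convergence), 4L)
  # elitist archive: best scalarized score never decreases
  expect_true(all(diff(arc$convergence$bestScalar) >= -1e-9))

  arc2 <- evolveModels(pd$X, pd$y, cfg)
  expect_identical(lapply(arc$members, `[[`, "fitness"),
                   lapply(arc2$members, `[[`, "fitness"))
  expect_identical(lapply(arc$members, `[[`, "chrom"),
                   lapply(arc2$members, `[[`, "chrom"))

  # degenerate config still runs
  tiny <- optimizerConfig(population = 2, generations = 1, nFolds = 3,
                          nRuns = 1, seed = 1)
  arcT <- evolveModels(pd$X[, 1:4], pd$y, tiny)
  expect_lte(length(arcT$members), 2 * 2)
})

test_that("doubling the feature-minimization weight shrinks models", {
  sizes <- matrix(NA_real_, 3, 2)
  for (s in 1:3) {
    pd <- makePlantedDataset(nPos = 20, nNeg = 20, nFeatures = 10,
                             nInformative = 2, effectSize = 2.5,
                             rho = 0, seed = 40 + s)
    cfg <- optimizerConfig(population = 8, generations = 3, nFolds = 4,
                           nRuns = 1, seed = s)
    for (wi in 1:2) {
      w <- goalWeights(featMin = c(5, 10)[wi])
      arc <- evolveModels(pd$X, pd$y, cfg, weights = w)
      sizes[s, wi] <- length(arc$members[[1]]$spec$features)
    }
  }
  expect_lte(mean(sizes[, 2]), mean(sizes[, 1]))
})

test_that("final training fits, isolates features and reproduces", {
  set.seed(20)
  n <- 40
  X <- cbind(sig = c(rnorm(n / 2, 2.5), rnorm(n / 2, -2.5)),
             other = rnorm(n))
  y <- rep(c(1L, 0L), each = n / 2)
  spec <- list(features = "sig", classifier = "svm", C = 10,
               gamma = 0.5, ntrees = 50L, feasible = TRUE)
  model <- trainFinal(spec, X, y, seed = 3)
  expect_s4_class(model, "UmamiModel")
  p <- predictProbability(model, X)
  expect_equal(unname(computeMetrics(y, p)$acc), 1)

  # single-feature model ignores perturbations of other columns
  X2 <- X; X2[, "other"] <- X2[, "other"] + 100
  expect_identical(predictProbability(model, X2), p)

  # refit under the same seed scores a probe set identically
  model2 <- trainFinal(spec, X, y, seed = 3)
  probe <- cbind(sig = seq(-3, 3, length.out = 11), other = 0)
  expect_identical(predictProbability(model, probe),
                   predictProbability(model2, probe))

  expect_error(trainFinal(list(feasible = FALSE), X, y), "infeasible")
})
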