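# Wilcoxon, kBest, mutual information, MRMR and JMIM.

test_that("Wilcoxon ranking reproduces the exact enumeration value", {
  X <- cbind(sep = c(1, 2, 3, 4, 5, 6), same = rep(1, 6))
  y <- c(1, 1, 1, 0, 0, 0)
  rk <- wilcoxonRank(X, y)
  # groups {1,2,3} vs {4,5,6}: exact two-sided p = 2/20
  expect_equal(rk$score[rk$feature == "sep"], 0.1)
  expect_equal(rk$score[rk$feature == "same"], 1)
  expect_identical(rk$feature[1], "sep")
  expect_setequal(rk$feature, colnames(X))

  # identical groups with ties: p = 1 under the tie-corrected normal
  rkT <- wilcoxonRank(cbind(t = c(1, 2, 1, 2)), c(1, 1, 0, 0))
  expect_equal(rkT$score, 1)
})

test_that("kBest F scores match aov on a hand-checked toy", {
  set.seed(3)
  X <- cbind(good = c(5, 6, 5.5, 1, 0.8, 1.2), noise = rnorm(6))
  y <- c(1, 1, 1, 0, 0, 0)
  rk <- kbestRank(X, y)
  expect_identical(rk$feature[1], "good")
  for (j in 1:2) {
    f <- summary(stats::aov(X[, j] ~ factor(y)))[[1]]$`F value`[1]
    expect_equal(rk$score[rk$feature == colnames(X)[j]], f,
                 tolerance = 1e-10)
  }
  # a feature identical to the label has unbounded separation
  X2 <- cbind(label = as.numeric(y), noise = rnorm(6))
  rk2 <- kbestRank(X2, y)
  expect_identical(rk2$feature[1], "label")
})

test_that("mutual information behaves at the extremes", {
  y <- rep(c(0L, 1L), each = 100)
  # perfect dependence: MI = entropy of y = log 2
  expect_equal(mutualInformation(as.numeric(y), y), log(2),
               tolerance = 1e-12)
  # constant x carries nothing
  expect_equal(mutualInformation(rep(1, 200), y), 0)
  # independent x: small at large n
  set.seed(8)
  yBig <- rep(c(0L, 1L), each = 1000)
  expect_lt(mutualInformation(rnorm(2000), yBig), 0.02)
})

test_that("MRMR penalizes redundancy and honours k", {
  set.seed(12)
  n <- 120
  x1 <- rnorm(n)
  y <- as.integer(x1 + rnorm(n, sd = 0.4) > 0)
  X <- cbind(x1 = x1, x2 = x1, x3 = rnorm(n))  # x2 is an exact copy
  sel <- mrmrSelect(X, y, k = 2)
  expect_identical(sel$feature, c("x1", "x3"))
  expect_identical(mrmrSelect(X, y, k = 1)$feature, "x1")

  # all-identical features: deterministic lowest-index tie-break
  Xsame <- cbind(a = x1, b = x1, c = x1)
  expect_identical(mrmrSelect(Xsame, y, k = 2)$feature[1], "a")
})

test_that("JMIM finds XOR partners that no marginal test sees", {
  set.seed(9)
  n <- 400
  x1 <- sample(0:1, n, TRUE)
  x2 <- sample(0:1, n, TRUE)
  y <- as.integer(xor(x1, x2))
  X <- cbind(x1 = x1, x2 = x2, x3 = sample(0:1, n, TRUE))
  sel <- jmimSelect(X, y, k = 2, bins = 2)
  expect_setequal(sel$feature, c("x1", "x2"))

  # plainly predictive first pick
  y2 <- x1
  sel2 <- jmimSelect(cbind(x1 = x1, x2 = x2), y2, k = 2, bins = 2)
  expect_identical(sel2$feature[1], "x1")

  # k = F yields a full permutation
  sel3 <- jmimSelect(X, y, k = 3, bins = 2)
  expect_setequal(sel3$feature, colnames(X))
})

test_that("greedy selections match exhaustive search of their criteria", {
  # brute-force greedy re-implementations over discretized columns
  bruteGreedy <- function(X, y, k, bins, type) {
    disc <- lapply(seq_len(ncol(X)), function(j)
      UmamiQSAR:::.discretize(X[, j], bins))
    rel <- vapply(disc, function(d) UmamiQSAR:::.miXY(d, y), numeric(1))
    sel <- integer(0)
    for (step in seq_len(k)) {
      cand <- setdiff(seq_len(ncol(X)), sel)
      crit <- vapply(cand, function(j) {
        if (!length(sel)) return(rel[j])
        if (type == "mrmr") {
          rel[j] - mean(vapply(sel, function(s)
            UmamiQSAR:::.miTable(table(disc[[j]], disc[[s]])),
            numeric(1)))
        } else {
          min(vapply(sel, function(s)
            UmamiQSAR:::.miJoint(disc[[j]], disc[[s]], y), numeric(1)))
        }
      }, numeric(1))
      sel <- c(sel, cand[which.max(crit)])
    }
    colnames(X)[sel]
  }
  set.seed(21)
  for (rep in 1:5) {
    n <- 80
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.5) > 0)
    expect_identical(mrmrSelect(X, y, k = 4)$feature,
                     bruteGreedy(X, y, 4, 10, "mrmr"))
    expect_identical(jmimSelect(X, y, k = 4)$feature,
                     bruteGreedy(X, y, 4, 10, "jmim"))
  }
})

test_that("every method puts a perfectly separating feature first", {
  pd <- makePlantedDataset(nPos = 30, nNeg = 30, nFeatures = 6,
                           nInformative = 1, effectSize = 20, rho = 0,
                           seed = 14)
  X <- pd$X; y <- pd$y
  expect_identical(wilcoxonRank(X, y)$feature[1], pd$informative)
  expect_identical(kbestRank(X, y)$feature[1], pd$informative)
  expect_identical(mrmrSelect(X, y, k = 1)$feature, pd$informative)
  expect_identical(jmimSelect(X, y, k = 1)$feature, pd$informative)
})

test_that("ranked features serialize to CSV", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- rep(c(0L, 1L), 10)
  tmp <- tempfile(fileext = ".csv")
  writeRankedCsv(wilcoxonRank(X, y), tmp)
  back <- read.csv(tmp)
  expect_identical(names(back), c("method", "rank", "feature", "score"))
  expect_identical(nrow(back), 2L)
})
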