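# Moderated t-test, empirical-Bayes prior, BH adjustment and feature
# prioritization.

test_that("log2 fold change handles the basic cases", {
  X <- cbind(a = c(4, 4, 1, 1), b = c(2, 2, 2, 2), c = c(1, 1, 2, 2))
  y <- c(1, 1, 0, 0)
  fc <- log2FoldChange(X, y)
  expect_equal(unname(fc), c(2, 0, -1))
  expect_error(log2FoldChange(X, c(1, 1, 1, 1)), "both classes")
})

test_that("eBayes prior: degenerate and simulated recovery", {
  pr <- fitEbayesPrior(rep(0.25, 10), dg = 4)
  expect_identical(pr@d0, Inf)
  expect_equal(pr@s0sq, 0.25)

  pr2 <- fitEbayesPrior(c(1, 1), dg = 4)
  expect_identical(pr2@d0, Inf)
  expect_equal(pr2@s0sq, 1)

  expect_error(fitEbayesPrior(c(0, 0), dg = 4), "zero")

  # variances drawn from the generating model: s2/s0 ~ F(dg, d0)
  set.seed(31)
  d0 <- 8; s0 <- 0.05; dg <- 10
  s2 <- s0 * stats::rf(2000, dg, d0)
  rec <- fitEbayesPrior(s2, dg)
  expect_lt(abs(rec@d0 - d0) / d0, 0.15)
  expect_lt(abs(rec@s0sq - s0) / s0, 0.15)
})

test_that("moderated t reduces to known limits", {
  set.seed(11)
  X <- matrix(rnorm(6 * 20), 6, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- c(1, 1, 1, 0, 0, 0)

  # d0 -> 0: ordinary pooled two-sample t
  st0 <- moderatedTTest(X, y, prior = new("EBayesPrior", d0 = 1e-12,
                                          s0sq = 1))
  tOrd <- vapply(1:20, function(j)
    stats::t.test(X[y == 1, j], X[y == 0, j],
                  var.equal = TRUE)$statistic, numeric(1))
  expect_equal(unname(st0$t), unname(tOrd), tolerance = 1e-6)

  # d0 -> Inf: shrunken variance is the prior for every feature
  stInf <- moderatedTTest(X, y, prior = new("EBayesPrior", d0 = Inf,
                                            s0sq = 0.5))
  seExp <- sqrt(0.5 * (1 / 3 + 1 / 3))
  expect_equal(stInf$t, (st0$mean_pos - st0$mean_neg) / seExp,
               tolerance = 1e-12)
})

test_that("moderated t agrees with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  # fixed 6-sample toy (3 vs 3)
  X <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(NULL, paste0("f", 1:40)))
  X[1:3, 1:4] <- X[1:3, 1:4] + 1.5
  y <- c(1, 1, 1, 0, 0, 0)
  mine <- featureStats(X, y)
  fit <- limma::eBayes(limma::lmFit(t(X), cbind(1, y)))
  expect_equal(mine$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(mine$q, unname(stats::p.adjust(fit$p.value[, 2], "BH")),
               tolerance = 1e-6)

  # larger random instance, finite prior
  X2 <- matrix(rnorm(30 * 200, sd = rep(runif(200, 0.5, 2), each = 30)),
               30, 200, dimnames = list(NULL, paste0("g", 1:200)))
  y2 <- rep(c(1, 0), each = 15)
  mine2 <- moderatedTTest(X2, y2)
  fit2 <- limma::eBayes(limma::lmFit(t(X2), cbind(1, y2)))
  expect_gt(fitEbayesPrior(mine2$s2, 28)@d0, 0)
  expect_equal(mine2$p, unname(fit2$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated t sign and monotonicity follow the mean difference", {
  set.seed(5)
  X <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c(1, 0), each = 20)
  st <- moderatedTTest(X, y)
  expect_true(all(sign(st$t) == sign(st$mean_pos - st$mean_neg) |
                    st$t == 0))

  # increasing the mean difference at fixed variances grows |t|
  prior <- new("EBayesPrior", d0 = 4, s0sq = 1)
  X2 <- X; X2[y == 1, 1] <- X2[y == 1, 1] + 5
  t1 <- abs(moderatedTTest(X, y, prior)$t[1])
  t2 <- abs(moderatedTTest(X2, y, prior)$t[1])
  expect_gt(t2, t1)
})

test_that("BH adjustment matches hand computation and is order-stable", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(1), 1)
  expect_error(bhAdjust(c(0.5, 1.5)), "\\[0,1\\]")

  set.seed(13)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("BH adjustment equals the brute-force suffix minimum", {
  bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- vapply(seq_len(m), function(i)
      min(ps[i:m] * m / (i:m), 1), numeric(1))
    q[order(o)]
  }
  set.seed(17)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("prioritization filters, orders and breaks ties stably", {
  st <- data.frame(feature = c("b", "a", "c", "d"),
                   log2FC = c(1, -2, 0.5, 3),
                   q = c(0.01, 0.01, 0.2, 0.04))
  out <- prioritizeFeatures(st, qThreshold = 0.05)
  expect_identical(out, c("a", "b", "d"))  # q asc, |FC| desc, name

  stAll1 <- data.frame(feature = letters[1:3], log2FC = 1:3,
                       q = rep(1, 3))
  expect_identical(prioritizeFeatures(stAll1), character(0))
})

test_that("planted informative features are found with high power", {
  hits <- 0L
  for (s in 1:20) {
    pd <- makePlantedDataset(nPos = 50, nNeg = 50, nFeatures = 100,
                             nInformative = 5, effectSize = 2,
                             rho = 0, seed = s)
    st <- suppressWarnings(featureStats(pd$X, pd$y))
    sel <- prioritizeFeatures(st)
    if (all(pd$informative %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
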