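# Missing filter, kNN imputation, min-max normalization, oversampling and
# stratified folds.

mkTable <- function(values) {
  UmamiQSAR:::.DescriptorTable(values)
}

test_that("missing filter drops strictly-above-threshold features", {
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("keep3", "drop4", "full", "edge")))
  X[1:4, "drop4"] <- NA   # 0.4 > 0.3 -> dropped
  X[1:3, "keep3"] <- NA   # 0.3, not > 0.3 -> kept
  X[1:3, "edge"] <- NA
  res <- filterMissing(mkTable(X), maxMissingFrac = 0.30)
  expect_identical(res$dropped, "drop4")
  expect_identical(descFeatureNames(res$table), c("keep3", "full", "edge"))

  # fully observed table is untouched
  Y <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  res2 <- filterMissing(mkTable(Y))
  expect_identical(res2$dropped, character(0))
  expect_identical(descValues(res2$table), Y)

  Z <- matrix(NA_real_, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(filterMissing(mkTable(Z)), "all features")
})

test_that("kNN imputation fills with neighbour means and only those", {
  # all neighbours carry value 5 at the missing feature
  X <- matrix(c(1, 5, 1.1, 5, 0.9, 5, 1.05, NA), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  imp <- knnImpute(mkTable(X), k = 20)
  expect_equal(unname(descValues(imp)[4, "b"]), 5)
  expect_identical(descValues(imp)[1:3, ], X[1:3, ])

  # no missing values: identity
  Y <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(descValues(knnImpute(mkTable(Y))), Y)

  # 3-row toy, k larger than available neighbours: mean of the two
  Z <- matrix(c(0, 10, 1, 20, 0.5, NA), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  impZ <- knnImpute(mkTable(Z), k = 20)
  expect_equal(unname(descValues(impZ)[3, "b"]), 15)  # hand mean of 10 and 20

  # a row with nothing observed cannot be imputed
  W <- matrix(c(1, 2, NA, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  expect_error(knnImpute(mkTable(W)), "r2")
})

test_that("kNN uses the nearest rows under shared-feature distance", {
  # target row is near rows 1-2 (value ~0) and far from rows 4-5
  X <- matrix(c(0, 100,
                0.1, 110,
                50, 900,
                50.2, 950,
                0.05, NA), 5, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  imp <- knnImpute(mkTable(X), k = 2)
  expect_equal(unname(descValues(imp)[5, "b"]), 105)  # mean of the 2 nearest
})

test_that("min-max normalization fits, freezes, maps and clips", {
  X <- matrix(c(2, 4, 6, 3, 3, 3), 3, 2,
              dimnames = list(NULL, c("v", "const")))
  params <- fitMinmax(mkTable(X))
  norm <- applyMinmax(mkTable(X), params)
  expect_equal(unname(descValues(norm)[, "v"]), c(0, 0.5, 1))
  expect_equal(unname(descValues(norm)[, "const"]), c(0, 0, 0))
  expect_true(isNormalized(norm))

  # out-of-range new data clips into [0, 1]
  Xnew <- matrix(c(8, -1, 3, 3), 2, 2,
                 dimnames = list(NULL, c("v", "const")))
  normNew <- applyMinmax(mkTable(Xnew), params)
  expect_equal(unname(descValues(normNew)[, "v"]), c(1, 0))

  # applying before fitting is an error
  unfitted <- new("PreprocessParams")
  expect_error(applyMinmax(mkTable(X), unfitted), "before fit")

  # fit refuses tables with missing cells (order is fixed)
  Xm <- X; Xm[1, 1] <- NA
  expect_error(fitMinmax(mkTable(Xm)), "imputed")
})

test_that("oversampling equalizes to the majority count", {
  # the documented study condition: 240 non-umami + 112 umami -> 240/240
  X <- matrix(0, 352, 1)
  y <- c(rep(0L, 240), rep(1L, 112))
  os <- randomOversample(X, y, seed = 4)
  expect_identical(sum(os$y == 0L), 240L)
  expect_identical(sum(os$y == 1L), 240L)
  expect_identical(os$index[1:352], 1:352)  # originals retained in order

  # balanced input unchanged
  yb <- rep(c(0L, 1L), each = 10)
  osb <- randomOversample(matrix(0, 20, 1), yb, seed = 1)
  expect_identical(length(osb$y), 20L)

  # 3 majority + 1 minority: the single minority row appears 3 times
  y31 <- c(0L, 0L, 0L, 1L)
  os31 <- randomOversample(matrix(1:4, 4, 1), y31, seed = 99)
  expect_identical(sum(os31$y == 1L), 3L)
  expect_true(all(os31$X[os31$y == 1L, 1] == 4))

  expect_error(randomOversample(matrix(0, 3, 1), c(1L, 1L, 1L)),
               "both classes")
})

test_that("oversampling is seeded and majority-invariant over seeds", {
  y <- c(rep(0L, 25), rep(1L, 7))
  X <- matrix(seq_along(y), ncol = 1)
  a <- randomOversample(X, y, seed = 11)
  b <- randomOversample(X, y, seed = 11)
  expect_identical(a$index, b$index)
  for (s in 1:5) {
    os <- randomOversample(X, y, seed = s)
    expect_identical(sum(os$y == 0L), 25L)
    expect_identical(sum(os$y == 1L), 25L)
    expect_true(all(os$X[os$y == 0L, 1] == which(y == 0L)))
  }
})

test_that("stratified folds balance classes within one sample", {
  y <- c(rep(1L, 20), rep(0L, 40))
  f <- stratifiedKfold(y, nFolds = 10, seed = 2)
  for (k in 1:10) {
    expect_identical(sum(y[f == k] == 1L), 2L)
    expect_identical(sum(y[f == k] == 0L), 4L)
  }
  expect_identical(stratifiedKfold(y, 10, seed = 2),
                   stratifiedKfold(y, 10, seed = 2))

  # 21 positives over 10 folds: counts in {2, 3}
  y2 <- c(rep(1L, 21), rep(0L, 30))
  f2 <- stratifiedKfold(y2, 10, seed = 3)
  posCounts <- vapply(1:10, function(k) sum(y2[f2 == k] == 1L),
                      integer(1))
  expect_true(all(posCounts %in% c(2L, 3L)))
  expect_identical(sum(posCounts), 21L)

  expect_error(stratifiedKfold(c(0L, 1L), nFolds = 5), "folds")
})

test_that("the fitted transform maps the training table into [0,1]", {
  pd <- makePlantedDataset(nPos = 10, nNeg = 15, nFeatures = 8,
                           missingFrac = 0.1, seed = 21)
  dt <- mkTable(pd$X)
  flt <- filterMissing(dt)
  imp <- knnImpute(flt$table, k = 3)
  params <- fitMinmax(imp)
  norm <- applyMinmax(imp, params)
  v <- descValues(norm)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(any(v == 0) && any(v == 1))  # extremes hit exactly
})
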