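# Classical per-pixel classifiers: training contracts, decision rules,
# importances, persistence, determinism.

trainingAccuracy <- function(model, X, y, h, w) {
  stack <- syntheticStack(X, h, w, bankId = bankId(model))
  mask <- classifyPixels(model, stack)$mask
  mean(as.integer(t(pixels(mask))) == y)
}

test_that("hyperparameter defaults reproduce the published table", {
  rf <- classicHyperparams("RF")
  expect_equal(rf@params$n_estimators, 100L)
  xgb <- classicHyperparams("XGB")
  expect_equal(xgb@params[c("n_estimators", "max_depth", "subsample")],
               list(n_estimators = 100L, max_depth = 4L, subsample = 0.5))
  svm <- classicHyperparams("SVM")
  expect_equal(svm@params[c("kernel", "degree", "gamma", "cache_mb")],
               list(kernel = "polynomial", degree = 3L, gamma = "scale",
                    cache_mb = 5000L))
  mlp <- classicHyperparams("MLP")
  expect_equal(mlp@params$hidden_layers, c(50L, 25L))
  expect_equal(mlp@params$n_iter_no_change, 50L)
  expect_equal(classicHyperparams("LDA")@params$solver, "svd")
  expect_error(classicHyperparams("RF", bogus = 1), "unknown hyperparameter")
})

test_that("threshold-separable data is learned by RF, XGB, MLP and LDA", {
  set.seed(20)
  h <- 24L; w <- 24L; n <- h * w
  X <- cbind(runif(n, 0, 255), matrix(runif(n * 3, 0, 255), n))
  y <- as.integer(X[, 1] > 128)
  pm <- syntheticPixelMatrix(X, y, h, w)
  for (m in c("RF", "XGB", "MLP", "LDA")) {
    fit <- trainPixelClassifier(pm, m, seed = 0)
    expect_gte(trainingAccuracy(fit, X, y, h, w), 0.99)
  }
})

test_that("XOR labels separate trees from the best linear rule", {
  d <- xorPixelData(1024L)
  pm <- syntheticPixelMatrix(d$X, d$y, 32L, 32L)
  rf <- trainPixelClassifier(pm, "RF", seed = 0)
  lda <- trainPixelClassifier(pm, "LDA", seed = 0)
  accRf <- trainingAccuracy(rf, d$X, d$y, 32L, 32L)
  accLda <- trainingAccuracy(lda, d$X, d$y, 32L, 32L)
  expect_gte(accRf, 0.95)
  expect_lte(accLda, 0.60)
  expect_gt(accRf, accLda)
})

test_that("degenerate training input is rejected", {
  X <- matrix(runif(40), 20, 2); colnames(X) <- c("f1", "f2")
  pm0 <- new("PixelMatrix", data = X, labels = rep(0L, 20),
             imageIndex = rep(1L, 20), bankId = "b")
  expect_error(trainPixelClassifier(pm0, "RF"), "single class")
})

test_that("classification preserves shape and guards bank provenance", {
  pairs <- easyPairs(5, canvas = 24L, seed = 30)
  bank <- buildDefaultBank()
  stacks <- stacksFor(pairs, bank)
  pm <- flattenDataset(stacks[1:4], masksFor(pairs[1:4]))
  fit <- trainPixelClassifier(pm, "RF", seed = 0)
  out <- classifyPixels(fit, stacks[[5]])
  expect_identical(dim(out$mask), c(24L, 24L))
  expect_identical(dim(out$scoreMap), c(24L, 24L))
  expect_true(all(out$scoreMap >= 0 & out$scoreMap <= 1))
  wrong <- new("FeatureStack", values = stacks[[5]]@values,
               bankId = "other-bank")
  expect_error(classifyPixels(fit, wrong), "bank mismatch")
})

test_that("held-out classification recovers the generating rule", {
  set.seed(21)
  h <- 24L; w <- 24L; n <- h * w
  Xtr <- cbind(runif(n, 0, 255), matrix(runif(n, 0, 255), n))
  ytr <- as.integer(Xtr[, 1] > 128)
  fit <- trainPixelClassifier(syntheticPixelMatrix(Xtr, ytr, h, w), "RF",
                              seed = 0)
  Xte <- cbind(runif(n, 0, 255), matrix(runif(n, 0, 255), n))
  yte <- as.integer(Xte[, 1] > 128)
  expect_gte(trainingAccuracy(fit, Xte, yte, h, w), 0.99)
})

test_that("tree-ensemble importances normalize, ignore constants, and
           are refused elsewhere", {
  set.seed(22)
  n <- 600L
  X <- cbind(runif(n, 0, 255), matrix(runif(n * 2, 0, 255), n),
             rep(42, n))  # last column constant
  y <- as.integer(X[, 1] > 128)
  pm <- syntheticPixelMatrix(X, y, 20L, 30L)
  for (m in c("RF", "XGB")) {
    fit <- trainPixelClassifier(pm, m, seed = 0)
    imp <- featureImportances(fit)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    expect_true(all(imp$importance >= 0))
    expect_false(is.unsorted(rev(imp$importance)))
    expect_lte(imp$importance[imp$id == "f4"], 1e-6)
    expect_equal(imp$id[1], "f1")
  }
  lda <- trainPixelClassifier(pm, "LDA", seed = 0)
  expect_error(featureImportances(lda), "unsupported")
})

test_that("SVM trains with the scale-gamma heuristic and scores in [0,1]", {
  set.seed(23)
  n <- 400L
  X <- cbind(runif(n, 0, 255), runif(n, 0, 255))
  y <- as.integer(X[, 1] > 128)
  pm <- syntheticPixelMatrix(X, y, 20L, 20L)
  fit <- trainPixelClassifier(pm, "SVM", seed = 0)
  out <- classifyPixels(fit, syntheticStack(X, 20L, 20L))
  expect_true(all(out$scoreMap >= 0 & out$scoreMap <= 1))
  expect_true(all(pixels(out$mask) %in% c(0, 1)))
})

test_that("model persistence is behavior-preserving and validated", {
  pairs <- easyPairs(4, canvas = 20L, seed = 33)
  stacks <- stacksFor(pairs)
  pm <- flattenDataset(stacks[1:3], masksFor(pairs[1:3]))
  probe <- stacks[[4]]
  for (m in c("RF", "XGB")) {
    fit <- trainPixelClassifier(pm, m, seed = 0)
    before <- pixels(classifyPixels(fit, probe)$mask)
    f <- withr::local_tempfile(fileext = ".bin")
    saveModel(fit, f)
    back <- loadModel(f)
    expect_identical(pixels(classifyPixels(back, probe)$mask), before)
  }
  expect_error(loadModel(file.path(tempdir(), "missing.bin")), "not found")
  bad <- withr::local_tempfile(fileext = ".bin")
  writeLines("not a model", bad)
  expect_error(loadModel(bad), "corrupted|unrecognized")
  f2 <- withr::local_tempfile(fileext = ".bin")
  saveModel(trainPixelClassifier(pm, "RF", seed = 0), f2)
  expect_error(loadModel(f2, expectedBankId = "some-other-bank"),
               "does not match")
})

test_that("training is deterministic under a fixed seed", {
  pairs <- easyPairs(4, canvas = 20L, seed = 34)
  stacks <- stacksFor(pairs)
  pm <- flattenDataset(stacks[1:3], masksFor(pairs[1:3]))
  for (m in c("RF", "XGB", "MLP")) {
    m1 <- trainPixelClassifier(pm, m, seed = 5)
    m2 <- trainPixelClassifier(pm, m, seed = 5)
    expect_identical(pixels(classifyPixels(m1, stacks[[4]])$mask),
                     pixels(classifyPixels(m2, stacks[[4]])$mask))
  }
})
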