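# U-Net construction, parameter accounting, training behavior, inference.

tinyCfg <- function(canvas = 16L)
  unetConfig(canvas = canvas, encoderWidths = c(2L, 3L, 4L, 5L),
             bottleneckWidth = 6L, threshold = 0.7)

tinyScenes <- function(n, seed = 0L) {
  spec <- sceneSpec(canvas = 16L, dropletCount = c(1L, 3L))
  pairs <- generateDataset(spec, n, seed = seed)
  list(images = lapply(pairs, function(p)
         padToCanvas(normalizeToUint8(p@image), 16L)$image),
       masks = lapply(pairs, function(p) padToCanvas(p@mask, 16L)$image),
       pairs = pairs)
}

test_that("parameter count matches the closed-form layer sum", {
  tiny <- buildUnet(tinyCfg(), seed = 0)
  expect_equal(countTrainableParameters(tiny),
               unetParamFormula(c(2, 3, 4, 5), 6))
  red <- buildUnet(reducedUnetConfig(), seed = 0)
  expect_equal(countTrainableParameters(red),
               unetParamFormula(c(8, 16, 32, 64), 128))
  # first convolution alone: (3*3*1 + 1) * width
  expect_equal(length(tiny@layers$enc1a$W) + length(tiny@layers$enc1a$b),
               (9 * 1 + 1) * 2)
  l1 <- buildUnet(unetConfig(canvas = 32L, encoderWidths = c(64L, 4L, 4L, 4L),
                             bottleneckWidth = 4L), seed = 0)@layers$enc1a
  expect_equal(length(l1$W) + length(l1$b), 640)
})

test_that("parameter count is invariant to canvas size", {
  a <- buildUnet(unetConfig(canvas = 64L, encoderWidths = c(4L, 8L, 16L, 32L),
                            bottleneckWidth = 64L), seed = 0)
  b <- buildUnet(unetConfig(canvas = 128L, encoderWidths = c(4L, 8L, 16L, 32L),
                            bottleneckWidth = 64L), seed = 0)
  expect_equal(countTrainableParameters(a), countTrainableParameters(b))
})

test_that("invalid canvas sizes are rejected", {
  expect_error(unetConfig(canvas = 100L), "divisible by 16")
  expect_error(unetConfig(threshold = 1.2), "threshold")
})

test_that("training reduces the loss on easy scenes", {
  sc <- tinyScenes(12, seed = 40)
  net <- buildUnet(tinyCfg(), seed = 0)
  fit <- trainUnet(net, sc$images, sc$masks, epochs = 6, seed = 0)
  expect_equal(fit$record@epochs, 6L)
  expect_length(fit$record@loss, 6L)
  expect_true(all(fit$record@loss >= 0))
  expect_lt(tail(fit$record@loss, 1), fit$record@loss[1])
})

test_that("training is deterministic given the seed", {
  sc <- tinyScenes(6, seed = 41)
  net <- buildUnet(tinyCfg(), seed = 1)
  f1 <- trainUnet(net, sc$images, sc$masks, epochs = 3, seed = 2)
  f2 <- trainUnet(net, sc$images, sc$masks, epochs = 3, seed = 2)
  expect_identical(f1$record@loss, f2$record@loss)
  expect_identical(f1$model@layers$dec9b$W, f2$model@layers$dec9b$W)
})

test_that("positive-free labels drive the net to all-negative output", {
  sc <- tinyScenes(10, seed = 42)
  empty <- lapply(sc$masks, function(m) binaryMask(pixels(m) * 0))
  net <- buildUnet(tinyCfg(), seed = 0)
  fit <- trainUnet(net, sc$images, empty, epochs = 8, seed = 0)
  for (i in 1:3) {
    seg <- segmentImage(fit$model, sc$pairs[[i]]@image)
    expect_true(all(pixels(seg$mask) == 0))
  }
})

test_that("segmentation restores original dimensions and thresholds by >=", {
  sc <- tinyScenes(6, seed = 43)
  net <- buildUnet(tinyCfg(), seed = 0)
  fit <- trainUnet(net, sc$images, sc$masks, epochs = 2, seed = 0)
  img <- qpiImage(pixels(sc$pairs[[1]]@image)[1:13, 1:10])
  seg <- segmentImage(fit$model, img)
  expect_identical(dim(seg$mask), c(13L, 10L))
  expect_identical(dim(seg$prob), c(13L, 10L))
  expect_true(all(seg$prob > 0 & seg$prob < 1))
  # mask is exactly the >= rule applied to the probability map
  expect_identical(pixels(seg$mask), (seg$prob >= 0.7) * 1)
  # monotone non-increasing in the threshold
  m5 <- pixels(segmentImage(fit$model, img, threshold = 0.5)$mask)
  m9 <- pixels(segmentImage(fit$model, img, threshold = 0.9)$mask)
  expect_true(all(m9 <= pixels(seg$mask)))
  expect_true(all(pixels(seg$mask) <= m5))
  big <- qpiImage(matrix(0, 20, 20))
  expect_error(segmentImage(fit$model, big), "larger than canvas")
})

test_that("U-Net weights persist through save/load", {
  sc <- tinyScenes(4, seed = 44)
  net <- buildUnet(tinyCfg(), seed = 0)
  fit <- trainUnet(net, sc$images, sc$masks, epochs = 2, seed = 0)
  f <- withr::local_tempfile(fileext = ".rds")
  saveUnet(fit$model, f)
  back <- loadUnet(f)
  p1 <- segmentImage(fit$model, sc$pairs[[1]]@image)$prob
  p2 <- segmentImage(back, sc$pairs[[1]]@image)$prob
  expect_identical(p1, p2)
})

test_that("dimension mismatches and empty training sets error", {
  sc <- tinyScenes(3, seed = 45)
  net <- buildUnet(tinyCfg(), seed = 0)
  expect_error(trainUnet(net, list(), list(), epochs = 1), "empty")
  badMask <- list(binaryMask(matrix(0, 8, 8)))
  expect_error(trainUnet(net, sc$images[1], badMask, epochs = 1),
               "canvas")
})
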