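# Image I/O, normalization, padding, projection, and the direct
# phase-thresholding baseline.

test_that("float TIFF round trip preserves phase values", {
  img <- qpiImage(matrix(0, 64, 64))
  f <- withr::local_tempfile(fileext = ".tif")
  writeGrayscaleTiff(img, f)
  back <- readGrayscaleTiff(f)
  expect_s4_class(back, "QPIImage")
  expect_identical(dim(back), c(64L, 64L))
  expect_true(all(pixels(back) == 0))

  set.seed(11)
  vals <- matrix(rnorm(30 * 17, sd = 4), 30, 17)  # well outside [0,1]
  vals32 <- matrix(readBin(writeBin(as.numeric(vals), raw(), size = 4),
                           numeric(), n = length(vals), size = 4),
                   30, 17)                         # float32 quantization
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeGrayscaleTiff(qpiImage(vals), f2)
  expect_identical(pixels(readGrayscaleTiff(f2)), vals32)
})

test_that("multi-band and missing TIFFs are rejected", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(12 * 12 * 3), c(12, 12, 3)), f)
  expect_error(readGrayscaleTiff(f), "multi-band")
  expect_error(readGrayscaleTiff(file.path(tempdir(), "absent.tif")),
               "not found")
})

test_that("masks store as 0/255 and round trip exactly", {
  f <- withr::local_tempfile(fileext = ".tif")
  writeMask(f, binaryMask(matrix(1, 4, 4)))
  expect_true(all(tiff::readTIFF(f, as.is = TRUE) == 255))
  writeMask(f, binaryMask(matrix(0, 4, 4)))
  expect_true(all(tiff::readTIFF(f, as.is = TRUE) == 0))
  set.seed(3)
  m <- binaryMask(matrix(rbinom(35, 1, 0.4), 5, 7))
  writeMask(f, m)
  expect_identical(pixels(readMask(f)), pixels(m))
})

test_that("max projection equals the per-pixel maximum", {
  one <- matrix(5, 3, 3)
  expect_identical(pixels(maxProject(list(one))), one)
  expect_true(all(pixels(maxProject(list(matrix(1, 4, 4),
                                         matrix(2, 4, 4)))) == 2))
  set.seed(4)
  slices <- lapply(1:5, function(i) matrix(rnorm(48), 6, 8))
  got <- pixels(maxProject(slices))
  for (i in 1:6) for (j in 1:8)
    expect_equal(got[i, j], max(vapply(slices, function(s) s[i, j],
                                       numeric(1))))
  expect_error(maxProject(list()), "at least one")
  expect_error(maxProject(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "same dimensions")
})

test_that("8-bit normalization uses round-half-up and handles zero range", {
  img <- qpiImage(matrix(c(-0.5, 0.5, 1.5, 1), 2, 2))
  norm <- normalizeToUint8(img)
  expect_equal(pixels(norm)[2, 1], 128)  # 127.5 rounds up
  expect_equal(pixels(norm)[1, 1], 0)
  expect_equal(pixels(norm)[1, 2], 255)
  expect_equal(norm@normParams, c(-0.5, 1.5))

  const <- normalizeToUint8(qpiImage(matrix(2.7, 3, 3)))
  expect_true(all(pixels(const) == 0))
  expect_equal(const@normParams, c(2.7, 2.7))
})

test_that("normalization is monotone in pixel value", {
  set.seed(5)
  v <- rnorm(400)
  out <- pixels(normalizeToUint8(qpiImage(matrix(v, 20, 20))))
  ord <- order(v)
  expect_true(all(diff(as.vector(out)[ord]) >= 0))
})

test_that("canvas padding centres content, sends remainders right/bottom, and inverts", {
  p1 <- padToCanvas(binaryMask(matrix(0, 80, 100)), 256L)
  expect_equal(c(p1$pad@left, p1$pad@right, p1$pad@top, p1$pad@bottom),
               c(78, 78, 88, 88))
  p2 <- padToCanvas(binaryMask(matrix(0, 80, 101)), 256L)
  expect_equal(c(p2$pad@left, p2$pad@right), c(77, 78))
  full <- matrix(runif(256 * 256), 256)
  p3 <- padToCanvas(normalizeToUint8(qpiImage(full)), 256L)
  expect_equal(c(p3$pad@left, p3$pad@right, p3$pad@top, p3$pad@bottom),
               rep(0, 4))
  expect_error(padToCanvas(binaryMask(matrix(0, 300, 10)), 256L),
               "larger than canvas")

  set.seed(6)
  for (dims in list(c(1, 1), c(5, 9), c(64, 64), c(63, 10))) {
    m <- matrix(as.numeric(rbinom(prod(dims), 1, 0.5)), dims[1], dims[2])
    pd <- padToCanvas(binaryMask(m), 64L)
    expect_identical(dim(pd$image), c(64L, 64L))
    expect_identical(pixels(unpadFromCanvas(pd$image, pd$pad)), m)
  }
})

test_that("direct phase thresholding uses the >= rule and is monotone in cutoff", {
  expect_true(all(pixels(directPhaseThreshold(qpiImage(matrix(1, 3, 3)),
                                              2)) == 0))
  expect_equal(pixels(directPhaseThreshold(qpiImage(matrix(2, 1, 1)),
                                           2))[1, 1], 1)
  spec <- sceneSpec(canvas = 32L, noiseSd = 0)
  pair <- generateScene(spec, seed = 9)
  got <- directPhaseThreshold(pair@image, 2)
  expect_identical(pixels(got), pixels(pair@mask))

  set.seed(7)
  img <- qpiImage(matrix(rnorm(100), 10))
  cuts <- sort(rnorm(5))
  masks <- lapply(cuts, function(ct) pixels(directPhaseThreshold(img, ct)))
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
})
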