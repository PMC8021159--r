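# Filter bank composition, filter correctness against dense-convolution
# oracles, and dataset flattening.

test_that("default bank has 80 filters, identity first, and unique ids", {
  bank <- buildDefaultBank()
  expect_equal(nFilters(bank), 80L)
  expect_equal(bank@specs[[1]]@family, "identity")
  ids <- filterIds(bank)
  expect_false(anyDuplicated(ids) > 0)
  fams <- vapply(bank@specs, function(s) s@family, character(1))
  expect_equal(unname(table(fams)["gaussian"]), 9L)
  expect_equal(unname(table(fams)["difference_of_gaussians"]), 8L)
  expect_equal(unname(table(fams)["structure_tensor_eig_large"]), 9L)
  expect_equal(unname(table(fams)["intensity_threshold"]), 8L)
})

test_that("bank serialization round trips identically", {
  bank <- buildDefaultBank()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeFilterBank(bank, f)
  back <- readFilterBank(f)
  expect_equal(bankId(back), bankId(bank))
  expect_equal(filterIds(back), filterIds(bank))
  for (i in seq_len(nFilters(bank))) {
    expect_equal(back@specs[[i]]@family, bank@specs[[i]]@family)
    expect_equal(back@specs[[i]]@params, bank@specs[[i]]@params)
  }
})

test_that("feature stack has bank depth and retains the input as layer 1", {
  pair <- generateScene(scenePreset("easy", canvas = 32L), seed = 2)
  norm <- normalizeToUint8(pair@image)
  stack <- applyBank(norm)
  expect_identical(dim(stack), c(32L, 32L, 80L))
  expect_identical(stack@values[, , 1], pixels(norm))
  expect_identical(stack@values[, , "identity"], pixels(norm))
})

test_that("derivative-family layers vanish on a constant image", {
  const <- new("NormalizedImage", pixels = matrix(7, 16, 16),
               normParams = c(0, 255))
  stack <- applyBank(const)
  bank <- buildDefaultBank()
  fams <- vapply(bank@specs, function(s) s@family, character(1))
  derivFams <- c("difference_of_gaussians", "laplacian_of_gaussian",
                 "sobel_of_gaussian", "gradient_magnitude",
                 "structure_tensor_eig_large", "structure_tensor_eig_small")
  for (j in which(fams %in% derivFams))
    expect_lt(max(abs(stack@values[, , j])), 1e-8)
})

test_that("gaussian layer matches the dense spatial-convolution oracle", {
  set.seed(13)
  px <- matrix(runif(28 * 28, 0, 255), 28)
  img <- new("NormalizedImage", pixels = round(px), normParams = c(0, 255))
  bank <- buildDefaultBank()
  j <- which(filterIds(bank) == "gaussian_s1.6")
  stack <- applyBank(img, bank)
  k1 <- dropseg:::.gaussianKernel1d(1.6, 0L)
  k2d <- outer(k1, k1)
  ref <- bruteFilter2(pixels(img), k2d)
  expect_lt(max(abs(stack@values[, , j] - ref)) / max(abs(ref)), 1e-10)
})

test_that("filters are translation-consistent away from borders", {
  set.seed(14)
  base <- matrix(runif(40 * 40, 0, 255), 40)
  shifted <- base[c(3:40, 1:2), c(2:40, 1)]  # shift up 2, left 1
  bank <- buildDefaultBank()
  sub <- new("FilterBank", specs = bank@specs[c(4, 12, 20, 30, 40, 46)],
             bankId = "sub")
  s1 <- applyBank(new("NormalizedImage", pixels = round(base),
                      normParams = c(0, 255)), sub)
  s2 <- applyBank(new("NormalizedImage", pixels = round(shifted),
                      normParams = c(0, 255)), sub)
  # generous interior margin clears every kernel radius in the subset
  core1 <- s1@values[15:34, 15:34, ]
  core2 <- s2@values[13:32, 14:33, ]
  expect_lt(max(abs(core1 - core2)), 1e-8)
})

test_that("flattening concatenates images row-major with aligned labels", {
  set.seed(15)
  mk <- function(h, w) {
    X <- matrix(runif(h * w * 3), h * w, 3)
    list(stack = syntheticStack(X, h, w, bankId = "b3"),
         mask = binaryMask(matrix(rbinom(h * w, 1, 0.5), h, w)))
  }
  a <- mk(4, 4); b <- mk(2, 3)
  pm <- flattenDataset(list(a$stack, b$stack), list(a$mask, b$mask))
  expect_equal(dim(pm@data), c(22L, 3L))
  expect_equal(pm@imageIndex, rep(c(1L, 2L), c(16L, 6L)))
  # row-major: row 2 of the matrix is pixel (1,2) of image a
  expect_equal(unname(pm@data[2, ]), unname(a$stack@values[1, 2, ]))
  expect_equal(pm@labels[2], as.integer(pixels(a$mask)[1, 2]))
  # last row is pixel (2,3) of image b
  expect_equal(unname(pm@data[22, ]), unname(b$stack@values[2, 3, ]))

  one <- mk(1, 1)
  pm1 <- flattenDataset(list(one$stack), list(one$mask))
  expect_equal(dim(pm1@data), c(1L, 3L))
  expect_equal(unname(pm1@data[1, ]), unname(one$stack@values[1, 1, ]))

  bad <- mk(4, 5)
  expect_error(flattenDataset(list(bad$stack), list(a$mask)), "mismatch"
  )
  k2 <- syntheticStack(matrix(runif(32), 16, 2), 4, 4, bankId = "b3")
  expect_error(flattenDataset(list(a$stack, k2), list(a$mask, a$mask)),
               "mixed feature depths")
})

test_that("unflattening reconstructs every stack exactly", {
  pairs <- easyPairs(3, canvas = 24L, seed = 6)
  bank <- buildDefaultBank()
  stacks <- stacksFor(pairs, bank)
  pm <- flattenDataset(stacks, masksFor(pairs))
  back <- unflattenDataset(pm, lapply(stacks, function(s) dim(s)[1:2]))
  for (i in seq_along(stacks))
    expect_equal(back[[i]]@values, stacks[[i]]@values)
})

test_that("default bank applied to a 64x64 image yields a 64x64x80 stack", {
  pair <- generateScene(scenePreset("easy"), seed = 1)
  stack <- applyBank(normalizeToUint8(pair@image))
  expect_identical(dim(stack), c(64L, 64L, 80L))
})
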