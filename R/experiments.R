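# Evaluation protocols: unshuffled k-fold cross-validation and
# training-set-size sweeps over a fixed held-out test set.

#' Experiment configuration
#'
#' @param kFolds fold count (default 5, unshuffled contiguous folds).
#' @param trainingSizes training-set sizes for [trainingSizeSweep()].
#' @param methods methods to evaluate (subset of RF, XGB, SVM, MLP, LDA,
#'   CNN).
#' @param seed base RNG seed.
#' @param epochs CNN training epochs (default 30 for the reduced network).
#' @param bank filter bank for the classical methods.
#' @param unet U-Net configuration for the CNN method (reduced by default).
#' @param numThreads advisory thread cap.
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(kFolds = 5L, trainingSizes = c(20L, 50L, 100L),
                             methods = c("RF", "XGB"), seed = 0L,
                             epochs = 30L, bank = buildDefaultBank(),
                             unet = reducedUnetConfig(),
                             numThreads = 1L) {
  new("ExperimentConfig", kFolds = as.integer(kFolds),
      trainingSizes = as.integer(trainingSizes), methods = methods,
      seed = as.integer(seed), epochs = as.integer(epochs), bank = bank,
      unet = unet, numThreads = as.integer(numThreads))
}

#' Split indices into k contiguous unshuffled folds
#'
#' Folds are contiguous in input order (no shuffling), disjoint and
#' covering; when n is not a multiple of k the larger folds come first.
#'
#' @param n item count (>= k).
#' @param k fold count (>= 2).
#' @return list of k lists, each with `train` and `validation` index
#'   vectors.
#' @export
kfoldSplit <- function(n, k) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop(sprintf("cannot split %d items into %d folds", n, k))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- starts[i]:ends[i]
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}

# Normalize an image set and compute feature stacks once, shared by folds.
.prepareStacks <- function(pairs, bank) {
  lapply(pairs, function(p) applyBank(normalizeToUint8(p@image), bank))
}

.pairMasks <- function(pairs) lapply(pairs, function(p) p@mask)

# Train one method on a set of pairs (stacks precomputed for classical
# methods) and return a function(image index) -> predicted mask.
.trainOn <- function(method, pairs, stacks, trainIdx, cfg, seed) {
  if (method == "CNN") {
    canvas <- cfg@unet@canvas
    imgs <- lapply(pairs[trainIdx], function(p) {
      padToCanvas(normalizeToUint8(p@image), canvas)$image
    })
    msks <- lapply(pairs[trainIdx], function(p)
      padToCanvas(p@mask, canvas)$image)
    net <- buildUnet(cfg@unet, seed = seed)
    fit <- trainUnet(net, imgs, msks, epochs = cfg@epochs, seed = seed)
    function(i) segmentImage(fit$model, pairs[[i]]@image)$mask
  } else {
    pm <- flattenDataset(stacks[trainIdx], .pairMasks(pairs[trainIdx]))
    hp <- classicHyperparams(method)
    model <- trainPixelClassifier(pm, hp, seed = seed)
    function(i) classifyPixels(model, stacks[[i]])$mask
  }
}

#' k-fold cross-validation of one method
#'
#' Contiguous unshuffled folds; each fold trains on the other k-1 folds
#' and is scored on its hold-out images. Per-fold scores are per-image
#' means (uninterpretable NaN scores excluded); pooled pixel counts per
#' fold are also reported. Fold means are averaged across folds the same
#' way.
#'
#' @param pairs list of [SyntheticPair-class] (or any objects with `image`
#'   and `mask` slots).
#' @param method one of RF, XGB, SVM, MLP, LDA, CNN.
#' @param cfg an [ExperimentConfig-class].
#' @return a [CVResult-class].
#' @export
crossValidate <- function(pairs, method, cfg = experimentConfig()) {
  n <- length(pairs)
  folds <- kfoldSplit(n, cfg@kFolds)
  stacks <- if (method == "CNN") NULL else .prepareStacks(pairs, cfg@bank)
  foldScores <- matrix(NA_real_, cfg@kFolds, length(.metricNames),
                       dimnames = list(NULL, .metricNames))
  pooled <- vector("list", cfg@kFolds)
  for (f in seq_along(folds)) {
    trainIdx <- folds[[f]]$train
    trainLabels <- unlist(lapply(pairs[trainIdx],
                                 function(p) range(p@mask@pixels)))
    if (length(unique(trainLabels)) < 2L)
      stop("training fold ", f, " contains a single class")
    predictFor <- .trainOn(method, pairs, stacks, trainIdx, cfg,
                           seed = cfg@seed + f - 1L)
    reports <- lapply(folds[[f]]$validation, function(i)
      scoreMasks(predictFor(i), pairs[[i]]@mask))
    avg <- averageMetrics(reports)
    foldScores[f, ] <- avg$means
    cells <- Reduce(`+`, lapply(reports, function(r)
      c(r@counts@tp, r@counts@tn, r@counts@fp, r@counts@fn)))
    pooled[[f]] <- computeMetrics(new("ConfusionCounts", tp = cells[1],
                                      tn = cells[2], fp = cells[3],
                                      fn = cells[4]))
  }
  means <- apply(foldScores, 2, function(col) mean(col[!is.nan(col)]))
  new("CVResult", method = method, foldScores = foldScores, means = means,
      exclusions = colSums(is.nan(foldScores)), pooled = pooled)
}

#' Training-set-size sweep against a fixed held-out test set
#'
#' For each method and size, draws a seeded subsample (without
#' replacement) from the training pool, trains, scores every test image,
#' and reports the median Dice coefficient over test images
#' (uninterpretable NaN Dice values excluded).
#'
#' @param trainPairs training pool (disjoint from the test set).
#' @param testPairs fixed held-out test pairs.
#' @param sizes training-set sizes, each <= the pool size.
#' @param methods methods to evaluate.
#' @param cfg an [ExperimentConfig-class].
#' @return data.frame with columns method, size, median_dice.
#' @export
trainingSizeSweep <- function(trainPairs, testPairs,
                              sizes = c(20L, 50L, 100L),
                              methods = c("RF", "XGB"),
                              cfg = experimentConfig()) {
  if (any(sizes < 1)) stop("training sizes must be positive")
  if (max(sizes) > length(trainPairs))
    stop(sprintf("size %d exceeds the training pool (%d images)",
                 max(sizes), length(trainPairs)))
  bank <- cfg@bank
  poolStacks <- .prepareStacks(trainPairs, bank)
  testStacks <- .prepareStacks(testPairs, bank)
  allPairs <- c(trainPairs, testPairs)
  allStacks <- c(poolStacks, testStacks)
  testIdx <- length(trainPairs) + seq_along(testPairs)
  rows <- list()
  for (method in methods) {
    for (s in sizes) {
      set.seed(.deriveSeed(cfg@seed, s + 13 * match(method, methods)))
      sub <- sample(seq_along(trainPairs), s)
      predictFor <- .trainOn(method, allPairs, allStacks, sub, cfg,
                             seed = cfg@seed)
      dice <- vapply(testIdx, function(i)
        scores(scoreMasks(predictFor(i), allPairs[[i]]@mask))[["dice"]],
        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, size = s,
        median_dice = median(dice[!is.nan(dice)]))
    }
  }
  do.call(rbind, rows)
}
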