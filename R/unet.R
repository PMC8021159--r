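# U-Net dialect for single-channel binary segmentation, with an in-package
# CPU training engine (im2col convolutions, hand-derived backward pass,
# Adam, binary cross-entropy).
#
# Architecture: encoder of 4 blocks of paired 3x3 same-padded biased ReLU
# convolutions at widths 64/128/256/512, each followed by 2x2 max pooling,
# with dropout after the 512 block; a 1024-wide bottleneck (two 3x3 convs +
# dropout); a decoder of 4 stages of 2x2 nearest upsampling -> 2x2 ReLU
# convolution -> concatenation with the matching encoder output -> paired
# 3x3 convolutions; and a head of one 3x3 two-filter convolution plus a
# 1x1 sigmoid output. With the default configuration this sums to exactly
# 31,031,685 trainable parameters.

#' U-Net architecture configuration
#'
#' @param canvas input side length; must be divisible by 16 (default 256).
#' @param inChannels input channel count (default 1).
#' @param encoderWidths filter counts of the four encoder blocks.
#' @param bottleneckWidth filter count at the bottleneck (default 1024).
#' @param dropoutRate dropout probability at the two deepest blocks
#'   (default 0.5, active only during training).
#' @param threshold probability cutoff for the binary mask (default 0.7;
#'   the >= rule is used).
#' @return a [UNetConfig-class].
#' @export
unetConfig <- function(canvas = 256L, inChannels = 1L,
                       encoderWidths = c(64L, 128L, 256L, 512L),
                       bottleneckWidth = 1024L,
                       dropoutRate = 0.5, threshold = 0.7) {
  new("UNetConfig", canvas = as.integer(canvas),
      inChannels = as.integer(inChannels),
      encoderWidths = as.integer(encoderWidths),
      bottleneckWidth = as.integer(bottleneckWidth),
      dropoutRate = dropoutRate, threshold = threshold)
}

#' Reduced U-Net configuration for CPU-scale experiments
#'
#' The same architecture with all widths divided by 8 and a 64-pixel
#' canvas; small enough to train in minutes on one CPU while preserving
#' every structural property of the full network.
#'
#' @param canvas input side length (default 64).
#' @param threshold probability cutoff (default 0.7).
#' @return a [UNetConfig-class].
#' @export
reducedUnetConfig <- function(canvas = 64L, threshold = 0.7) {
  unetConfig(canvas = canvas, encoderWidths = c(8L, 16L, 32L, 64L),
             bottleneckWidth = 128L, threshold = threshold)
}

# Ordered layer geometry for a configuration: name, kernel, in/out
# channels, padding, activation.
.unetLayerDefs <- function(cfg) {
  w <- cfg@encoderWidths; wb <- cfg@bottleneckWidth; cin <- cfg@inChannels
  defs <- list()
  add <- function(defs, name, kh, kw, ci, co, relu = TRUE) {
    pt <- if (kh == 3L) 1L else 0L  # 'same' padding; even kernels pad
    pl <- if (kw == 3L) 1L else 0L  # the extra pixel at bottom/right
    c(defs, list(list(name = name, kh = kh, kw = kw, cin = ci, cout = co,
                      pt = pt, pl = pl, relu = relu)))
  }
  defs <- add(defs, "enc1a", 3L, 3L, cin, w[1]); defs <- add(defs, "enc1b", 3L, 3L, w[1], w[1])
  defs <- add(defs, "enc2a", 3L, 3L, w[1], w[2]); defs <- add(defs, "enc2b", 3L, 3L, w[2], w[2])
  defs <- add(defs, "enc3a", 3L, 3L, w[2], w[3]); defs <- add(defs, "enc3b", 3L, 3L, w[3], w[3])
  defs <- add(defs, "enc4a", 3L, 3L, w[3], w[4]); defs <- add(defs, "enc4b", 3L, 3L, w[4], w[4])
  defs <- add(defs, "bot_a", 3L, 3L, w[4], wb);  defs <- add(defs, "bot_b", 3L, 3L, wb, wb)
  defs <- add(defs, "up6", 2L, 2L, wb, w[4])
  defs <- add(defs, "dec6a", 3L, 3L, 2L * w[4], w[4]); defs <- add(defs, "dec6b", 3L, 3L, w[4], w[4])
  defs <- add(defs, "up7", 2L, 2L, w[4], w[3])
  defs <- add(defs, "dec7a", 3L, 3L, 2L * w[3], w[3]); defs <- add(defs, "dec7b", 3L, 3L, w[3], w[3])
  defs <- add(defs, "up8", 2L, 2L, w[3], w[2])
  defs <- add(defs, "dec8a", 3L, 3L, 2L * w[2], w[2]); defs <- add(defs, "dec8b", 3L, 3L, w[2], w[2])
  defs <- add(defs, "up9", 2L, 2L, w[2], w[1])
  defs <- add(defs, "dec9a", 3L, 3L, 2L * w[1], w[1]); defs <- add(defs, "dec9b", 3L, 3L, w[1], w[1])
  defs <- add(defs, "head_a", 3L, 3L, w[1], 2L)
  defs <- add(defs, "head_out", 1L, 1L, 2L, 1L, relu = FALSE)
  defs
}

#' Build a U-Net model
#'
#' Allocates He-initialized weights for every convolution of the dialect.
#' Convolutional parameter counts are independent of the canvas size.
#'
#' @param cfg a [UNetConfig-class] (default configuration if omitted).
#' @param seed RNG seed for weight initialization.
#' @return a [UNetModel-class].
#' @export
buildUnet <- function(cfg = unetConfig(), seed = 0L) {
  stopifnot(is(cfg, "UNetConfig"))
  set.seed(seed)
  layers <- list()
  for (d in .unetLayerDefs(cfg)) {
    fanIn <- d$kh * d$kw * d$cin
    layers[[d$name]] <- list(
      W = matrix(rnorm(fanIn * d$cout, sd = sqrt(2 / fanIn)), fanIn, d$cout),
      b = rep(0, d$cout),
      kh = d$kh, kw = d$kw, pt = d$pt, pl = d$pl, relu = d$relu)
  }
  new("UNetModel", layers = layers, config = cfg, seed = as.integer(seed))
}

#' Count trainable parameters of a built model
#'
#' Sums weights and biases over all convolutional layers by walking the
#' layer graph; pooling, upsampling, dropout and concatenation carry no
#' parameters.
#'
#' @param model a [UNetModel-class].
#' @return integer parameter count.
#' @export
countTrainableParameters <- function(model) {
  stopifnot(is(model, "UNetModel"))
  sum(vapply(model@layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

.convF <- function(x, l) cpp_conv_fwd(x, l$W, l$b, l$kh, l$kw, l$pt, l$pl, l$relu)

.cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

.dropMask <- function(d, rate) {
  keep <- 1 - rate
  array((runif(prod(d)) < keep) / keep, dim = d)
}

# Forward pass; returns sigmoid probability map plus (optionally) every
# intermediate needed by the backward pass.
.unetForward <- function(layers, x, dropoutRate = 0, training = FALSE,
                         keepCache = FALSE) {
  cc <- list(x = x)
  cc$a1 <- .convF(x, layers$enc1a);  cc$e1 <- .convF(cc$a1, layers$enc1b)
  pl1 <- cpp_maxpool_fwd(cc$e1);     cc$am1 <- pl1$argmax
  cc$a2 <- .convF(pl1$out, layers$enc2a); cc$e2 <- .convF(cc$a2, layers$enc2b)
  cc$p1 <- pl1$out
  pl2 <- cpp_maxpool_fwd(cc$e2);     cc$am2 <- pl2$argmax; cc$p2 <- pl2$out
  cc$a3 <- .convF(cc$p2, layers$enc3a); cc$e3 <- .convF(cc$a3, layers$enc3b)
  pl3 <- cpp_maxpool_fwd(cc$e3);     cc$am3 <- pl3$argmax; cc$p3 <- pl3$out
  cc$a4 <- .convF(cc$p3, layers$enc4a); cc$e4 <- .convF(cc$a4, layers$enc4b)
  cc$m4 <- if (training && dropoutRate > 0) .dropMask(dim(cc$e4), dropoutRate) else NULL
  cc$d4 <- if (is.null(cc$m4)) cc$e4 else cc$e4 * cc$m4
  pl4 <- cpp_maxpool_fwd(cc$d4);     cc$am4 <- pl4$argmax; cc$p4 <- pl4$out
  cc$ba <- .convF(cc$p4, layers$bot_a); cc$bb <- .convF(cc$ba, layers$bot_b)
  cc$m5 <- if (training && dropoutRate > 0) .dropMask(dim(cc$bb), dropoutRate) else NULL
  cc$d5 <- if (is.null(cc$m5)) cc$bb else cc$bb * cc$m5

  cc$u6p <- cpp_upsample_fwd(cc$d5); cc$u6 <- .convF(cc$u6p, layers$up6)
  cc$m6 <- .cat3(cc$d4, cc$u6)
  cc$c6a <- .convF(cc$m6, layers$dec6a); cc$c6b <- .convF(cc$c6a, layers$dec6b)
  cc$u7p <- cpp_upsample_fwd(cc$c6b); cc$u7 <- .convF(cc$u7p, layers$up7)
  cc$m7 <- .cat3(cc$e3, cc$u7)
  cc$c7a <- .convF(cc$m7, layers$dec7a); cc$c7b <- .convF(cc$c7a, layers$dec7b)
  cc$u8p <- cpp_upsample_fwd(cc$c7b); cc$u8 <- .convF(cc$u8p, layers$up8)
  cc$m8 <- .cat3(cc$e2, cc$u8)
  cc$c8a <- .convF(cc$m8, layers$dec8a); cc$c8b <- .convF(cc$c8a, layers$dec8b)
  cc$u9p <- cpp_upsample_fwd(cc$c8b); cc$u9 <- .convF(cc$u9p, layers$up9)
  cc$m9 <- .cat3(cc$e1, cc$u9)
  cc$c9a <- .convF(cc$m9, layers$dec9a); cc$c9b <- .convF(cc$c9a, layers$dec9b)
  cc$h1 <- .convF(cc$c9b, layers$head_a)
  cc$logit <- .convF(cc$h1, layers$head_out)
  prob <- 1 / (1 + exp(-cc$logit))
  list(prob = prob, cache = if (keepCache) cc else NULL)
}

.convB <- function(l, x, out, g) cpp_conv_bwd(x, l$W, out, g, l$kh, l$kw,
                                              l$pt, l$pl, l$relu)

# Backward pass from dL/dlogit; returns per-layer weight/bias gradients.
.unetBackward <- function(layers, cc, dLogit) {
  gr <- list()
  w1 <- dim(cc$e1)[3]; w2 <- dim(cc$e2)[3]
  w3 <- dim(cc$e3)[3]; w4 <- dim(cc$e4)[3]

  r <- .convB(layers$head_out, cc$h1, cc$logit, dLogit)
  gr$head_out <- r; g <- r$dx
  r <- .convB(layers$head_a, cc$c9b, cc$h1, g); gr$head_a <- r; g <- r$dx
  r <- .convB(layers$dec9b, cc$c9a, cc$c9b, g); gr$dec9b <- r; g <- r$dx
  r <- .convB(layers$dec9a, cc$m9, cc$c9a, g); gr$dec9a <- r; g <- r$dx
  gSkip1 <- g[, , seq_len(w1), drop = FALSE]
  gU9 <- g[, , w1 + seq_len(w1), drop = FALSE]
  r <- .convB(layers$up9, cc$u9p, cc$u9, gU9); gr$up9 <- r
  g <- cpp_upsample_bwd(r$dx)

  r <- .convB(layers$dec8b, cc$c8a, cc$c8b, g); gr$dec8b <- r; g <- r$dx
  r <- .convB(layers$dec8a, cc$m8, cc$c8a, g); gr$dec8a <- r; g <- r$dx
  gSkip2 <- g[, , seq_len(w2), drop = FALSE]
  gU8 <- g[, , w2 + seq_len(w2), drop = FALSE]
  r <- .convB(layers$up8, cc$u8p, cc$u8, gU8); gr$up8 <- r
  g <- cpp_upsample_bwd(r$dx)

  r <- .convB(layers$dec7b, cc$c7a, cc$c7b, g); gr$dec7b <- r; g <- r$dx
  r <- .convB(layers$dec7a, cc$m7, cc$c7a, g); gr$dec7a <- r; g <- r$dx
  gSkip3 <- g[, , seq_len(w3), drop = FALSE]
  gU7 <- g[, , w3 + seq_len(w3), drop = FALSE]
  r <- .convB(layers$up7, cc$u7p, cc$u7, gU7); gr$up7 <- r
  g <- cpp_upsample_bwd(r$dx)

  r <- .convB(layers$dec6b, cc$c6a, cc$c6b, g); gr$dec6b <- r; g <- r$dx
  r <- .convB(layers$dec6a, cc$m6, cc$c6a, g); gr$dec6a <- r; g <- r$dx
  gSkip4 <- g[, , seq_len(w4), drop = FALSE]
  gU6 <- g[, , w4 + seq_len(w4), drop = FALSE]
  r <- .convB(layers$up6, cc$u6p, cc$u6, gU6); gr$up6 <- r
  gD5 <- cpp_upsample_bwd(r$dx)

  if (!is.null(cc$m5)) gD5 <- gD5 * cc$m5
  r <- .convB(layers$bot_b, cc$ba, cc$bb, gD5); gr$bot_b <- r; g <- r$dx
  r <- .convB(layers$bot_a, cc$p4, cc$ba, g); gr$bot_a <- r
  gD4 <- gSkip4 +
    cpp_maxpool_bwd(r$dx, cc$am4, dim(cc$d4)[1], dim(cc$d4)[2])
  if (!is.null(cc$m4)) gD4 <- gD4 * cc$m4
  r <- .convB(layers$enc4b, cc$a4, cc$e4, gD4); gr$enc4b <- r; g <- r$dx
  r <- .convB(layers$enc4a, cc$p3, cc$a4, g); gr$enc4a <- r
  gE3 <- gSkip3 +
    cpp_maxpool_bwd(r$dx, cc$am3, dim(cc$e3)[1], dim(cc$e3)[2])
  r <- .convB(layers$enc3b, cc$a3, cc$e3, gE3); gr$enc3b <- r; g <- r$dx
  r <- .convB(layers$enc3a, cc$p2, cc$a3, g); gr$enc3a <- r
  gE2 <- gSkip2 +
    cpp_maxpool_bwd(r$dx, cc$am2, dim(cc$e2)[1], dim(cc$e2)[2])
  r <- .convB(layers$enc2b, cc$a2, cc$e2, gE2); gr$enc2b <- r; g <- r$dx
  r <- .convB(layers$enc2a, cc$p1, cc$a2, g); gr$enc2a <- r
  gE1 <- gSkip1 +
    cpp_maxpool_bwd(r$dx, cc$am1, dim(cc$e1)[1], dim(cc$e1)[2])
  r <- .convB(layers$enc1b, cc$a1, cc$e1, gE1); gr$enc1b <- r; g <- r$dx
  r <- .convB(layers$enc1a, cc$x, cc$a1, g); gr$enc1a <- r
  gr
}

.asUnetInput <- function(img, canvas) {
  px <- if (is(img, "NormalizedImage")) img@pixels / 255
        else if (is(img, "BinaryMask")) img@pixels
        else img
  if (!identical(dim(px), c(canvas, canvas)))
    stop(sprintf("input is %dx%d but the model canvas is %d",
                 nrow(px), ncol(px), canvas))
  px
}

#' Train a U-Net with minibatch Adam on binary cross-entropy
#'
#' Streams the training set in batches (memory use is bounded by the batch,
#' not the dataset), records the mean per-epoch loss, and is fully
#' deterministic given the seed: shuffling, dropout and initialization all
#' draw from the seeded R RNG.
#'
#' @param model a built [UNetModel-class].
#' @param images list of canvas-sized inputs: [NormalizedImage-class]
#'   (scaled internally to \[0,1\]) or numeric matrices already in \[0,1\].
#' @param masks list of canvas-sized [BinaryMask-class] (or 0/1 matrices).
#' @param epochs number of full passes over the training set.
#' @param batchSize minibatch size (default 2).
#' @param seed RNG seed (default 0).
#' @param lr Adam learning rate (default 1e-4).
#' @param verbose print the per-epoch loss.
#' @return list with `model` (trained) and `record` ([TrainRecord-class]).
#' @export
trainUnet <- function(model, images, masks, epochs, batchSize = 2L,
                      seed = 0L, lr = 1e-4, verbose = FALSE) {
  stopifnot(is(model, "UNetModel"))
  n <- length(images)
  if (n < 1L) stop("empty training set")
  if (length(masks) != n) stop("images and masks must have equal length")
  canvas <- model@config@canvas
  xs <- lapply(images, .asUnetInput, canvas = canvas)
  ys <- lapply(masks, .asUnetInput, canvas = canvas)
  layers <- model@layers
  rate <- model@config@dropoutRate

  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8; stepN <- 0L
  st <- lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  lossHist <- numeric(epochs)
  npix <- canvas * canvas

  set.seed(seed)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      acc <- NULL
      batchLoss <- 0
      for (i in idx) {
        x <- array(xs[[i]], dim = c(canvas, canvas, 1L))
        y <- ys[[i]]
        fw <- .unetForward(layers, x, dropoutRate = rate, training = TRUE,
                           keepCache = TRUE)
        p <- pmin(pmax(fw$prob[, , 1], 1e-7), 1 - 1e-7)
        batchLoss <- batchLoss - mean(y * log(p) + (1 - y) * log(1 - p))
        dLogit <- array((fw$prob[, , 1] - y) / (npix * length(idx)),
                        dim = c(canvas, canvas, 1L))
        gr <- .unetBackward(layers, fw$cache, dLogit)
        if (is.null(acc)) acc <- gr
        else for (nm in names(acc)) {
          acc[[nm]]$dW <- acc[[nm]]$dW + gr[[nm]]$dW
          acc[[nm]]$db <- acc[[nm]]$db + gr[[nm]]$db
        }
      }
      stepN <- stepN + 1L
      corr1 <- 1 - beta1^stepN; corr2 <- 1 - beta2^stepN
      for (nm in names(layers)) {
        gW <- acc[[nm]]$dW; gb <- acc[[nm]]$db
        st[[nm]]$mW <- beta1 * st[[nm]]$mW + (1 - beta1) * gW
        st[[nm]]$vW <- beta2 * st[[nm]]$vW + (1 - beta2) * gW^2
        st[[nm]]$mb <- beta1 * st[[nm]]$mb + (1 - beta1) * gb
        st[[nm]]$vb <- beta2 * st[[nm]]$vb + (1 - beta2) * gb^2
        layers[[nm]]$W <- layers[[nm]]$W -
          lr * (st[[nm]]$mW / corr1) / (sqrt(st[[nm]]$vW / corr2) + epsA)
        layers[[nm]]$b <- layers[[nm]]$b -
          lr * (st[[nm]]$mb / corr1) / (sqrt(st[[nm]]$vb / corr2) + epsA)
      }
      epochLoss <- epochLoss + batchLoss / length(idx)
      nb <- nb + 1L
    }
    lossHist[epoch] <- epochLoss / nb
    if (verbose)
      message(sprintf("epoch %d/%d  bce %.5f", epoch, epochs,
                      lossHist[epoch]))
  }
  trained <- new("UNetModel", layers = layers, config = model@config,
                 seed = model@seed)
  rec <- new("TrainRecord", epochs = as.integer(epochs), loss = lossHist,
             batchSize = as.integer(batchSize), seed = as.integer(seed),
             optimizer = list(name = "adam", lr = lr, beta1 = beta1,
                              beta2 = beta2))
  list(model = trained, record = rec)
}

#' Segment a phase image with a trained U-Net
#'
#' The image is min-max normalized, scaled to \[0,1\], zero-padded to the
#' model canvas, forward-passed (dropout inactive), and thresholded; both
#' the probability map and the mask are un-padded back to the original
#' dimensions.
#'
#' @param model a trained [UNetModel-class].
#' @param img a [QPIImage-class] (or [NormalizedImage-class]); must not
#'   exceed the canvas.
#' @param threshold optional override of the configured cutoff.
#' @return list with `prob` (matrix of sigmoid outputs, original size) and
#'   `mask` ([BinaryMask-class], probability >= threshold).
#' @export
segmentImage <- function(model, img, threshold = NULL) {
  stopifnot(is(model, "UNetModel"))
  thr <- if (is.null(threshold)) model@config@threshold else threshold
  norm <- if (is(img, "NormalizedImage")) img else normalizeToUint8(img)
  canvas <- model@config@canvas
  padded <- padToCanvas(norm, canvas)
  x <- array(padded$image@pixels / 255, dim = c(canvas, canvas, 1L))
  fw <- .unetForward(model@layers, x, training = FALSE)
  probCanvas <- fw$prob[, , 1]
  prob <- unpadFromCanvas(probCanvas, padded$pad)
  list(prob = prob, mask = binaryMask((prob >= thr) * 1))
}

.unetFormatVersion <- 1L

#' Save U-Net weights and configuration
#'
#' @param model a [UNetModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveUnet <- function(model, path) {
  saveRDS(list(format_version = .unetFormatVersion,
               config = list(canvas = model@config@canvas,
                             inChannels = model@config@inChannels,
                             encoderWidths = model@config@encoderWidths,
                             bottleneckWidth = model@config@bottleneckWidth,
                             dropoutRate = model@config@dropoutRate,
                             threshold = model@config@threshold),
               seed = model@seed, layers = model@layers), path)
  invisible(path)
}

#' Load U-Net weights saved with [saveUnet()]
#'
#' @param path path to the weights file.
#' @return a [UNetModel-class].
#' @export
loadUnet <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  blob <- readRDS(path)
  if (!identical(blob$format_version, .unetFormatVersion))
    stop("unrecognized U-Net weights format in ", path)
  cfgl <- blob$config
  cfg <- unetConfig(canvas = cfgl$canvas, inChannels = cfgl$inChannels,
                    encoderWidths = cfgl$encoderWidths,
                    bottleneckWidth = cfgl$bottleneckWidth,
                    dropoutRate = cfgl$dropoutRate,
                    threshold = cfgl$threshold)
  new("UNetModel", layers = blob$layers, config = cfg, seed = blob$seed)
}
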