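# Minimal dense-network engine backing the MLP method: fully-connected
# ReLU layers, sigmoid output, binary cross-entropy, Adam with minibatches,
# and an epochs-without-improvement halt condition.

.mlpInit <- function(sizes, seed) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fanIn <- sizes[i]
    list(W = matrix(rnorm(fanIn * sizes[i + 1], sd = sqrt(2 / fanIn)),
                    fanIn, sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

.mlpForward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  acts
}

.mlpFit <- function(X, y, hidden = c(50L, 25L), maxIter = 1000L,
                    patience = 50L, tol = 1e-4, batchSize = 200L,
                    lr = 1e-3, seed = 0L) {
  # standardize inputs; raw 8-bit feature scales otherwise saturate the
  # sigmoid head early in training
  mu <- colMeans(X)
  sdv <- pmax(sqrt(colMeans(X^2) - mu^2), 1e-8)
  X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, 1L)
  layers <- .mlpInit(sizes, seed)
  nl <- length(layers)
  mW <- lapply(layers, function(l) l$W * 0); vW <- mW
  mb <- lapply(layers, function(l) l$b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8; step <- 0L
  best <- Inf; since <- 0L
  bs <- min(batchSize, n)
  lossHist <- numeric(0)
  for (epoch in seq_len(maxIter)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      acts <- .mlpForward(layers, Xb)
      p <- pmin(pmax(acts[[nl + 1L]], 1e-12), 1 - 1e-12)
      epochLoss <- epochLoss - mean(yb * log(p) + (1 - yb) * log(1 - p))
      nb <- nb + 1L
      delta <- (acts[[nl + 1L]] - yb) / length(idx)   # dL/dZ at sigmoid
      step <- step + 1L
      for (i in rev(seq_len(nl))) {
        gW <- crossprod(acts[[i]], delta)
        gb <- colSums(delta)
        if (i > 1L)
          delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
        mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW
        vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gW^2
        mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * gb
        vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        layers[[i]]$W <- layers[[i]]$W -
          lr * (mW[[i]] / corr1) / (sqrt(vW[[i]] / corr2) + epsA)
        layers[[i]]$b <- layers[[i]]$b -
          lr * (mb[[i]] / corr1) / (sqrt(vb[[i]] / corr2) + epsA)
      }
    }
    epochLoss <- epochLoss / nb
    lossHist <- c(lossHist, epochLoss)
    if (epochLoss < best - tol) { best <- epochLoss; since <- 0L }
    else since <- since + 1L
    if (since >= patience) break
  }
  # converged = halted by the improvement criterion, not by the epoch cap
  list(layers = layers, loss = lossHist,
       converged = length(lossHist) < maxIter, hidden = hidden,
       center = mu, scale = sdv)
}

.mlpPredict <- function(fit, X) {
  X <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  acts <- .mlpForward(fit$layers, X)
  as.numeric(acts[[length(acts)]])
}
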