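# Shared fixtures and independent oracles used across the suite.

# Reflect an out-of-range index back into [1, n] (edge-duplicating mirror),
# matching the package's stated boundary convention.
reflectIdx <- function(i, n) {
  if (n == 1L) return(1L)
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period
  if (i >= n) i <- period - 1L - i
  i + 1L
}

# Brute-force dense 2D correlation with reflective boundary; the oracle for
# every convolution-family filter.
bruteFilter2 <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  rr <- (nrow(k) - 1L) / 2L; rc <- (ncol(k) - 1L) / 2L
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (u in -rr:rr) for (v in -rc:rc)
      s <- s + k[u + rr + 1L, v + rc + 1L] *
        x[reflectIdx(i + u, h), reflectIdx(j + v, w)]
    out[i, j] <- s
  }
  out
}

# Pairwise-ranking AUC oracle: fraction of positive/negative pairs ranked
# correctly, ties counting one half.
pairwiseAuc <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Direct evaluation of the six printed score formulas from raw counts.
bruteMetrics <- function(tp, tn, fp, fn) {
  P <- tp + fn; N <- tn + fp
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    balanced_accuracy = (tp / P + tn / N) / 2,
    precision = tp / (tp + fp),
    recall = tp / P,
    dice = 2 * tp / (2 * tp + fp + fn),
    jaccard = tp / (tp + fp + fn))
}

# Closed-form trainable-parameter total for the U-Net dialect.
unetParamFormula <- function(w = c(64, 128, 256, 512), wb = 1024, cin = 1) {
  conv <- function(k, ci, co) (k * k * ci + 1) * co
  total <- conv(3, cin, w[1]) + conv(3, w[1], w[1])
  for (i in 2:4) total <- total + conv(3, w[i - 1], w[i]) + conv(3, w[i], w[i])
  total <- total + conv(3, w[4], wb) + conv(3, wb, wb)
  prev <- wb
  for (i in 4:1) {
    total <- total + (2 * 2 * prev + 1) * w[i] +       # 2x2 up-convolution
      conv(3, 2 * w[i], w[i]) + conv(3, w[i], w[i])
    prev <- w[i]
  }
  total + conv(3, w[1], 2) + conv(1, 2, 1)
}

# Small synthetic datasets shared by classifier and harness tests.
easyPairs <- function(n, canvas = 32L, seed = 0L)
  generateDataset(scenePreset("easy", canvas = canvas), n, seed = seed)

stacksFor <- function(pairs, bank = buildDefaultBank())
  lapply(pairs, function(p) applyBank(normalizeToUint8(p@image), bank))

masksFor <- function(pairs) lapply(pairs, function(p) p@mask)

# A feature matrix wrapped as a 2-layer FeatureStack + PixelMatrix, for
# classifier tests that need exact control over the features.
syntheticPixelMatrix <- function(X, labels, h, w, bankId = "synthetic2") {
  stopifnot(nrow(X) == h * w)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  new("PixelMatrix", data = X, labels = as.integer(labels),
      imageIndex = rep(1L, nrow(X)), bankId = bankId)
}

syntheticStack <- function(X, h, w, bankId = "synthetic2") {
  vals <- aperm(array(X, dim = c(w, h, ncol(X))), c(2, 1, 3))
  dimnames(vals) <- list(NULL, NULL, paste0("f", seq_len(ncol(X))))
  new("FeatureStack", values = vals, bankId = bankId)
}

# XOR-patterned two-feature pixel data: no linear separator exceeds chance
# by much, while trees represent it exactly.
xorPixelData <- function(n = 1024L, seed = 7L) {
  set.seed(seed)
  X <- cbind(runif(n), runif(n), matrix(runif(n * 2), n))
  y <- as.integer(xor(X[, 1] > 0.5, X[, 2] > 0.5))
  list(X = X, y = y)
}
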