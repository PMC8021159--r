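# The 80-filter feature bank and dataset flattening.
#
# Every filter runs on the 8-bit normalized image and emits a real-valued
# response layer; boundary handling is reflection for all convolutions, so
# no spurious edge responses appear on padded borders. Filters are grouped
# in families over a fixed sigma ladder; the composition below totals
# exactly 80 layers with the untouched normalized image retained as the
# first layer.

.bankSigmas <- c(0.3, 0.7, 1.0, 1.6, 2.5, 3.5, 5.0, 7.5, 10.0)
.bankWindows <- c(3L, 5L, 7L, 9L, 11L, 15L, 19L, 25L, 31L)
.bankQuantiles <- seq(0.1, 0.8, by = 0.1)

# Sampled Gaussian (order 0) and Gaussian-derivative (orders 1, 2) kernels,
# radius 3*sigma, normalized so the response to 1, x, x^2/2 is exactly 1.
.gaussianKernel1d <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  xs <- (-r):r
  g <- exp(-xs^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -xs / sigma^2 * g
    return(k / sum(k * xs))
  }
  if (order == 2L) {
    k <- (xs^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k)
    return(k / sum(k * xs^2 / 2))
  }
  stop("unsupported derivative order")
}

.sobelX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)  # d/dx (columns)
.sobelY <- t(.sobelX)                                   # d/dy (rows)

# Apply one FilterSpec to a numeric pixel matrix.
.applyFilter <- function(spec, px, cache = NULL) {
  fam <- spec@family
  p <- spec@params
  smooth <- function(s) {
    key <- sprintf("g%.4f", s)
    if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE))
      return(get(key, envir = cache))
    k0 <- .gaussianKernel1d(s, 0L)
    out <- cpp_sepfilter(px, k0, k0)
    if (!is.null(cache)) assign(key, out, envir = cache)
    out
  }
  switch(fam,
    identity = px,
    gaussian = smooth(p$sigma),
    difference_of_gaussians = smooth(p$sigma_high) - smooth(p$sigma_low),
    laplacian_of_gaussian = {
      k0 <- .gaussianKernel1d(p$sigma, 0L)
      k2 <- .gaussianKernel1d(p$sigma, 2L)
      cpp_sepfilter(px, k2, k0) + cpp_sepfilter(px, k0, k2)
    },
    sobel_of_gaussian = {
      sm <- smooth(p$sigma)
      sqrt(cpp_filter2(sm, .sobelX)^2 + cpp_filter2(sm, .sobelY)^2)
    },
    gradient_magnitude = {
      k0 <- .gaussianKernel1d(p$sigma, 0L)
      k1 <- .gaussianKernel1d(p$sigma, 1L)
      gx <- cpp_sepfilter(px, k0, k1)
      gy <- cpp_sepfilter(px, k1, k0)
      sqrt(gx^2 + gy^2)
    },
    structure_tensor_eig_large = .structureTensorEig(px, p$sigma, cache)$large,
    structure_tensor_eig_small = .structureTensorEig(px, p$sigma, cache)$small,
    median = cpp_median_filter(px, p$window),
    intensity_threshold = {
      q <- quantile(px, p$quantile, names = FALSE)
      (px >= q) * 255
    },
    stop("unknown filter family: ", fam))
}

# Structure tensor at integration scale sigma: gradients from the 3x3 Sobel
# of the sigma-smoothed image, tensor entries smoothed at the same sigma,
# closed-form eigenvalues of the 2x2 tensor.
.structureTensorEig <- function(px, sigma, cache = NULL) {
  key <- sprintf("st%.4f", sigma)
  if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE))
    return(get(key, envir = cache))
  k0 <- .gaussianKernel1d(sigma, 0L)
  sm <- cpp_sepfilter(px, k0, k0)
  gx <- cpp_filter2(sm, .sobelX)
  gy <- cpp_filter2(sm, .sobelY)
  jxx <- cpp_sepfilter(gx * gx, k0, k0)
  jyy <- cpp_sepfilter(gy * gy, k0, k0)
  jxy <- cpp_sepfilter(gx * gy, k0, k0)
  tr <- (jxx + jyy) / 2
  d <- sqrt(((jxx - jyy) / 2)^2 + jxy^2)
  out <- list(large = tr + d, small = tr - d)
  if (!is.null(cache)) assign(key, out, envir = cache)
  out
}

#' Build the default 80-filter bank
#'
#' Composition (80 layers total, deterministic order):
#' \itemize{
#'   \item 1 identity layer (the retained normalized image);
#'   \item 9 Gaussian smoothings over sigma 0.3, 0.7, 1.0, 1.6, 2.5, 3.5,
#'     5.0, 7.5, 10.0;
#'   \item 8 differences of Gaussians over the consecutive sigma pairs;
#'   \item 9 Laplacian-of-Gaussian responses;
#'   \item 9 Sobel edge magnitudes after Gaussian smoothing;
#'   \item 9 Gaussian gradient magnitudes;
#'   \item 9 + 9 structure-tensor eigenvalues (large then small);
#'   \item 9 median filters over windows 3-31;
#'   \item 8 intensity-threshold maps at per-image quantiles 0.1-0.8.
#' }
#'
#' @return a [FilterBank-class] with `bankId` "default80".
#' @export
buildDefaultBank <- function() {
  sp <- function(id, family, ...) new("FilterSpec", id = id, family = family,
                                      params = list(...))
  specs <- list(sp("identity", "identity"))
  for (s in .bankSigmas)
    specs <- c(specs, sp(sprintf("gaussian_s%g", s), "gaussian", sigma = s))
  for (i in seq_len(length(.bankSigmas) - 1L))
    specs <- c(specs, sp(
      sprintf("dog_s%g_%g", .bankSigmas[i], .bankSigmas[i + 1]),
      "difference_of_gaussians",
      sigma_low = .bankSigmas[i], sigma_high = .bankSigmas[i + 1]))
  for (s in .bankSigmas)
    specs <- c(specs, sp(sprintf("log_s%g", s), "laplacian_of_gaussian",
                         sigma = s))
  for (s in .bankSigmas)
    specs <- c(specs, sp(sprintf("sobel_s%g", s), "sobel_of_gaussian",
                         sigma = s))
  for (s in .bankSigmas)
    specs <- c(specs, sp(sprintf("gradmag_s%g", s), "gradient_magnitude",
                         sigma = s))
  for (s in .bankSigmas)
    specs <- c(specs, sp(sprintf("st_large_s%g", s),
                         "structure_tensor_eig_large", sigma = s))
  for (s in .bankSigmas)
    specs <- c(specs, sp(sprintf("st_small_s%g", s),
                         "structure_tensor_eig_small", sigma = s))
  for (w in .bankWindows)
    specs <- c(specs, sp(sprintf("median_w%d", w), "median", window = w))
  for (q in .bankQuantiles)
    specs <- c(specs, sp(sprintf("thresh_q%g", q), "intensity_threshold",
                         quantile = q))
  new("FilterBank", specs = specs, bankId = "default80")
}

#' Serialize a filter bank to a YAML config file
#'
#' @param bank a [FilterBank-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFilterBank <- function(bank, path) {
  recs <- lapply(bank@specs, function(s)
    c(list(id = s@id, family = s@family), s@params))
  yaml::write_yaml(list(bank_id = bank@bankId, filters = recs), path)
  invisible(path)
}

#' Parse a filter bank from a YAML config file
#'
#' @param path path written by [writeFilterBank()].
#' @return a [FilterBank-class] identical to the serialized one.
#' @export
readFilterBank <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg$filters, function(r) {
    params <- r[setdiff(names(r), c("id", "family"))]
    if (length(params) == 0L) params <- list()
    if (!is.null(params$window)) params$window <- as.integer(params$window)
    new("FilterSpec", id = r$id, family = r$family, params = params)
  })
  new("FilterBank", specs = specs, bankId = cfg$bank_id)
}

#' Apply a filter bank to a normalized image
#'
#' Expands the 2D image into a (h, w, k) feature stack; layer j is filter j
#' applied to the image. Layers are named by filter id and Gaussian-family
#' intermediates are shared across families for speed.
#'
#' @param img a [NormalizedImage-class].
#' @param bank a [FilterBank-class] (default bank if omitted).
#' @return a [FeatureStack-class] with depth `nFilters(bank)`.
#' @export
applyBank <- function(img, bank = buildDefaultBank()) {
  stopifnot(is(img, "NormalizedImage"))
  if (length(bank@specs) == 0L) stop("empty filter bank")
  px <- img@pixels
  cache <- new.env(parent = emptyenv())
  layers <- lapply(bank@specs, .applyFilter, px = px, cache = cache)
  vals <- array(unlist(layers, use.names = FALSE),
                dim = c(nrow(px), ncol(px), length(layers)),
                dimnames = list(NULL, NULL, filterIds(bank)))
  new("FeatureStack", values = vals, bankId = bank@bankId)
}

# Row-major (by image rows) flattening of one (h, w, k) stack.
.flattenStack <- function(vals) {
  d <- dim(vals)
  m <- matrix(aperm(vals, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(vals)[[3]]
  m
}

#' Flatten feature stacks and masks into a training matrix
#'
#' Rows follow image order, then row-major order within each image; labels
#' are aligned 1:1 with rows.
#'
#' @param stacks list of [FeatureStack-class] objects with a common bank.
#' @param masks list of matching [BinaryMask-class] objects.
#' @return a [PixelMatrix-class].
#' @export
flattenDataset <- function(stacks, masks) {
  if (length(stacks) != length(masks))
    stop("stacks and masks must have equal length")
  if (length(stacks) == 0L) stop("empty dataset")
  ks <- vapply(stacks, function(s) dim(s@values)[3], numeric(1))
  if (length(unique(ks)) != 1L)
    stop("mixed feature depths across stacks: ", paste(unique(ks), collapse = ", "))
  bids <- unique(vapply(stacks, bankId, character(1)))
  if (length(bids) != 1L)
    stop("mixed bank ids across stacks: ", paste(bids, collapse = ", "))
  rows <- vector("list", length(stacks))
  labs <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    d <- dim(stacks[[i]]@values)
    md <- dim(masks[[i]]@pixels)
    if (!identical(d[1:2], md))
      stop(sprintf("image %d: dimension mismatch, stack %dx%d vs mask %dx%d",
                   i, d[1], d[2], md[1], md[2]))
    rows[[i]] <- .flattenStack(stacks[[i]]@values)
    labs[[i]] <- as.integer(t(masks[[i]]@pixels))
  }
  data <- do.call(rbind, rows)
  new("PixelMatrix", data = data,
      labels = unlist(labs),
      imageIndex = rep.int(seq_along(stacks),
                           vapply(rows, nrow, numeric(1))),
      bankId = bids)
}

#' Reconstruct per-image feature stacks from a flattened matrix
#'
#' The exact inverse of [flattenDataset()] given the original image
#' dimensions, used to verify that flattening conserves every pixel.
#'
#' @param pm a [PixelMatrix-class].
#' @param dims list of c(h, w) per image, in image order.
#' @return list of [FeatureStack-class] objects.
#' @export
unflattenDataset <- function(pm, dims) {
  ids <- sort(unique(pm@imageIndex))
  stopifnot(length(dims) == length(ids))
  lapply(seq_along(ids), function(i) {
    rows <- pm@data[pm@imageIndex == ids[i], , drop = FALSE]
    h <- dims[[i]][1]; w <- dims[[i]][2]
    vals <- aperm(array(rows, dim = c(w, h, ncol(rows))), c(2, 1, 3))
    dimnames(vals) <- list(NULL, NULL, colnames(pm@data))
    new("FeatureStack", values = vals, bankId = pm@bankId)
  })
}
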