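# Image input/output and the direct-thresholding baseline.
#
# Phase images travel as single-band 32-bit float TIFFs. Reading goes
# through the tiff package (which reads float samples faithfully); writing
# float data uses a minimal single-strip uncompressed writer because the
# available TIFF writers only store values inside [0, 1] reliably. Masks
# are stored as 8-bit TIFFs with 0/255 on disk and 0/1 in memory.

#' Construct a QPIImage from a numeric matrix
#'
#' @param pixels numeric matrix of finite phase values.
#' @param sourceId optional identifier (defaults to NA).
#' @return a [QPIImage-class].
#' @export
qpiImage <- function(pixels, sourceId = NA_character_) {
  storage.mode(pixels) <- "double"
  new("QPIImage", pixels = pixels, sourceId = sourceId)
}

#' Construct a BinaryMask from a 0/1 matrix
#'
#' @param pixels numeric matrix containing only 0 and 1.
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(pixels) {
  storage.mode(pixels) <- "double"
  new("BinaryMask", pixels = pixels)
}

#' Read a single-band grayscale TIFF as a phase image
#'
#' Multi-band (e.g. RGB) files are rejected, as are images containing
#' non-finite values.
#'
#' @param path path to a single-band TIFF (32-bit float for phase data;
#'   integer-sample files are read on the tiff package's \[0,1\] scale).
#' @return a [QPIImage-class].
#' @export
readGrayscaleTiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("not a readable TIFF: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L)
      stop("multi-band TIFF rejected (", dim(arr)[3], " bands): ", path)
    arr <- arr[, , 1L]
  }
  if (!all(is.finite(arr)))
    stop("image contains non-finite pixel values: ", path)
  qpiImage(arr, sourceId = basename(path))
}

#' Write a phase image as a 32-bit float grayscale TIFF
#'
#' Minimal single-strip uncompressed little-endian writer; preserves all
#' finite values exactly (round-trips bit-identically through
#' [readGrayscaleTiff()] up to float32 precision).
#'
#' @param img a [QPIImage-class] (or numeric matrix).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGrayscaleTiff <- function(img, path) {
  px <- if (is(img, "QPIImage")) img@pixels else img
  h <- nrow(px); w <- ncol(px)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  wr2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wr4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  n_entries <- 10L
  data_offset <- 8L + 2L + n_entries * 12L + 4L
  writeBin(charToRaw("II"), con); wr2(42L); wr4(8L)
  wr2(n_entries)
  entry(256L, 4L, 1L, w)                    # ImageWidth
  entry(257L, 4L, 1L, h)                    # ImageLength
  entry(258L, 3L, 1L, 32L)                  # BitsPerSample
  entry(259L, 3L, 1L, 1L)                   # Compression: none
  entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)          # StripOffsets
  entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
  entry(278L, 4L, 1L, h)                    # RowsPerStrip
  entry(279L, 4L, 1L, h * w * 4L)           # StripByteCounts
  entry(339L, 3L, 1L, 3L)                   # SampleFormat: IEEE float
  wr4(0L)                                   # no next IFD
  writeBin(as.numeric(t(px)), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (1 -> 255, 0 -> 0)
#'
#' @param path output path.
#' @param mask a [BinaryMask-class].
#' @return the path, invisibly.
#' @export
writeMask <- function(path, mask) {
  stopifnot(is(mask, "BinaryMask"))
  ok <- tryCatch({
    tiff::writeTIFF(mask@pixels, path, bits.per.sample = 8L)
    TRUE
  }, error = function(e) stop("cannot write mask to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read an 8-bit mask TIFF back into a BinaryMask
#'
#' Any strictly positive pixel is taken as lipid (1).
#'
#' @param path path to an 8-bit single-band TIFF.
#' @return a [BinaryMask-class].
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  binaryMask((arr > 0) * 1)
}

#' Maximum-intensity projection of a z-stack
#'
#' Compresses an ordered stack of same-sized 2D slices into a single 2D
#' image, keeping the per-pixel maximum across slices. This is the standard
#' reduction for 3D phase stacks whose axial resolution is lower than the
#' lateral one.
#'
#' @param stack a list of numeric matrices, all with identical dimensions,
#'   or a 3D array (h, w, slices).
#' @return a [QPIImage-class] of the elementwise maxima.
#' @export
maxProject <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack) || length(stack) == 0L)
    stop("stack must contain at least one slice")
  d <- dim(stack[[1]])
  if (!all(vapply(stack, function(s) identical(dim(s), d), logical(1))))
    stop("all slices must share the same dimensions")
  qpiImage(Reduce(pmax, stack))
}

#' Min-max normalize a phase image to 8 bits
#'
#' Maps v to round(255 (v - min) / (max - min)) with round-half-up
#' quantization. A constant image (zero range) maps to all 0: a constant
#' carries no signal and this avoids the divide-by-zero.
#'
#' @param img a [QPIImage-class] or finite numeric matrix.
#' @return a [NormalizedImage-class] with `normParams` = (min, max).
#' @export
normalizeToUint8 <- function(img) {
  px <- if (is(img, "QPIImage")) img@pixels else img
  if (!all(is.finite(px))) stop("image contains non-finite values")
  lo <- min(px); hi <- max(px)
  out <- if (lo == hi) array(0, dim(px)) else
    floor(255 * (px - lo) / (hi - lo) + 0.5)
  dim(out) <- dim(px)
  new("NormalizedImage", pixels = out, normParams = c(lo, hi))
}

.padAmounts <- function(h, w, canvas) {
  if (h > canvas || w > canvas)
    stop(sprintf("image (%dx%d) larger than canvas (%d); no cropping", h, w,
                 canvas))
  left <- (canvas - w) %/% 2L
  top <- (canvas - h) %/% 2L
  new("PadRecord", left = as.integer(left),
      right = as.integer(canvas - w - left),
      top = as.integer(top),
      bottom = as.integer(canvas - h - top),
      canvas = as.integer(canvas))
}

#' Pad an image or mask onto a square canvas
#'
#' Centres the content and fills the border with 0 (the background phase in
#' QPI is ~0, and masks are background-0). Odd remainders go to the right
#' and bottom. The returned [PadRecord-class] makes the operation exactly
#' invertible via [unpadFromCanvas()].
#'
#' @param x a [NormalizedImage-class], [BinaryMask-class],
#'   [QPIImage-class], or numeric matrix.
#' @param canvas target side length (default 256).
#' @return list with elements `image` (same class as `x`) and `pad`.
#' @export
padToCanvas <- function(x, canvas = 256L) {
  px <- if (is.matrix(x)) x else pixels(x)
  rec <- .padAmounts(nrow(px), ncol(px), canvas)
  out <- matrix(0, canvas, canvas)
  out[(rec@top + 1L):(canvas - rec@bottom),
      (rec@left + 1L):(canvas - rec@right)] <- px
  img <- if (is.matrix(x)) out
    else if (is(x, "NormalizedImage"))
      new("NormalizedImage", pixels = out, normParams = x@normParams)
    else if (is(x, "BinaryMask")) binaryMask(out)
    else qpiImage(out, sourceId = x@sourceId)
  list(image = img, pad = rec)
}

#' Invert canvas padding
#'
#' @param x the padded object returned by [padToCanvas()].
#' @param pad the matching [PadRecord-class].
#' @return the original-size object, exactly as before padding.
#' @export
unpadFromCanvas <- function(x, pad) {
  px <- if (is.matrix(x)) x else pixels(x)
  canvas <- pad@canvas
  core <- px[(pad@top + 1L):(canvas - pad@bottom),
             (pad@left + 1L):(canvas - pad@right), drop = FALSE]
  if (is.matrix(x)) core
  else if (is(x, "NormalizedImage"))
    new("NormalizedImage", pixels = core, normParams = x@normParams)
  else if (is(x, "BinaryMask")) binaryMask(core)
  else qpiImage(core, sourceId = x@sourceId)
}

#' Direct optical-phase thresholding baseline
#'
#' The classical label-free baseline: a pixel is lipid when its phase value
#' is greater than or equal to the cutoff.
#'
#' @param img a [QPIImage-class] or finite numeric matrix.
#' @param cutoff phase threshold (the >= rule is used, so a pixel exactly
#'   at the cutoff is positive).
#' @return a [BinaryMask-class].
#' @export
directPhaseThreshold <- function(img, cutoff) {
  px <- if (is(img, "QPIImage")) img@pixels else img
  if (!all(is.finite(px))) stop("image contains non-finite values")
  binaryMask((px >= cutoff) * 1)
}
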