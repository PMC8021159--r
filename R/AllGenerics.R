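#' Extract the pixel grid of an image-like object
#'
#' @param x a [QPIImage-class], [NormalizedImage-class], or
#'   [BinaryMask-class].
#' @return the underlying numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
setMethod("pixels", "QPIImage", function(x) x@pixels)
#' @rdname pixels
setMethod("pixels", "NormalizedImage", function(x) x@pixels)
#' @rdname pixels
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' Feature-provenance identifier
#'
#' @param x a [FilterBank-class], [FeatureStack-class], [PixelMatrix-class]
#'   or [TrainedPixelClassifier-class].
#' @return character bank id.
#' @export
setGeneric("bankId", function(x) standardGeneric("bankId"))

#' @rdname bankId
setMethod("bankId", "FilterBank", function(x) x@bankId)
#' @rdname bankId
setMethod("bankId", "FeatureStack", function(x) x@bankId)
#' @rdname bankId
setMethod("bankId", "PixelMatrix", function(x) x@bankId)
#' @rdname bankId
setMethod("bankId", "TrainedPixelClassifier", function(x) x@bankId)

#' Six-score vector of a metrics report
#'
#' @param x a [MetricsReport-class].
#' @return named numeric of accuracy, balanced_accuracy, precision, recall,
#'   dice, jaccard.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scores
setMethod("scores", "MetricsReport", function(x) x@scores)

#' Area under a ROC curve
#'
#' @param x a [RocCurve-class].
#' @return numeric AUC in \[0,1\].
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname auc
setMethod("auc", "RocCurve", function(x) x@auc)

#' @describeIn pixels dimensions of the pixel grid
#' @export
setMethod("dim", "QPIImage", function(x) dim(x@pixels))
#' @rdname pixels
setMethod("dim", "NormalizedImage", function(x) dim(x@pixels))
#' @rdname pixels
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))
#' @rdname pixels
setMethod("dim", "FeatureStack", function(x) dim(x@values))

#' Number of filters in a bank
#'
#' @param x a [FilterBank-class].
#' @return integer count.
#' @export
setGeneric("nFilters", function(x) standardGeneric("nFilters"))

#' @rdname nFilters
setMethod("nFilters", "FilterBank", function(x) length(x@specs))

#' Filter identifiers of a bank, in order
#'
#' @param x a [FilterBank-class].
#' @return character vector of ids.
#' @export
setGeneric("filterIds", function(x) standardGeneric("filterIds"))

#' @rdname filterIds
setMethod("filterIds", "FilterBank",
  function(x) vapply(x@specs, function(s) s@id, character(1)))

setMethod("show", "QPIImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("QPIImage %dx%d [%s], phase range [%.4g, %.4g]\n",
              d[1], d[2],
              ifelse(is.na(object@sourceId), "unnamed", object@sourceId),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "NormalizedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("NormalizedImage %dx%d (8-bit), source range [%.4g, %.4g]\n",
              d[1], d[2], object@normParams[1], object@normParams[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask %dx%d, %d positive pixels (%.2f%%)\n",
              d[1], d[2], sum(object@pixels),
              100 * mean(object@pixels)))
})

setMethod("show", "FilterBank", function(object) {
  fam <- table(vapply(object@specs, function(s) s@family, character(1)))
  cat(sprintf("FilterBank '%s' with %d filters\n", object@bankId,
              length(object@specs)))
  for (f in names(fam)) cat(sprintf("  %-28s %d\n", f, fam[[f]]))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureStack %dx%dx%d (bank '%s')\n",
              d[1], d[2], d[3], object@bankId))
})

setMethod("show", "PixelMatrix", function(object) {
  cat(sprintf("PixelMatrix: %d pixels x %d features from %d image(s); %.2f%% positive\n",
              nrow(object@data), ncol(object@data),
              length(unique(object@imageIndex)),
              100 * mean(object@labels)))
})

setMethod("show", "TrainedPixelClassifier", function(object) {
  s <- object@trainingSummary
  cat(sprintf("TrainedPixelClassifier [%s], bank '%s'\n",
              object@method, object@bankId))
  cat(sprintf("  trained on %d pixels (%.2f%% positive), seed %d\n",
              s$n, 100 * s$positive_fraction, s$seed))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  print(round(object@scores, 4))
  if (length(object@flags))
    cat("  uninterpretable:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n",
              length(object@fpr), object@auc))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: canvas %d, phases bg/cell/LD = %g/%g/%g, noise sd %g, blur %g\n",
              object@canvas, object@background, object@cell$phase,
              object@droplets$phase, object@noise$sd, object@noise$blur))
})

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel: canvas %d, widths %s + %d, %s trainable parameters\n",
              object@config@canvas,
              paste(object@config@encoderWidths, collapse = "/"),
              object@config@bottleneckWidth,
              format(countTrainableParameters(object), big.mark = ",")))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s], %d folds\n", object@method,
              nrow(object@foldScores)))
  print(round(object@means, 4))
})
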