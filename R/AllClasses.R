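# S4 classes for the segmentation pipeline. Images are stored as plain
# numeric matrices (rows = image rows, origin top-left); the classes add
# invariants and provenance on top.

#' QPIImage: a single-band quantitative-phase image
#'
#' Pixel values are real-valued optical phase delays in arbitrary phase
#' units; background is typically near 0 and lipid droplets carry the
#' highest phase. All values must be finite.
#'
#' @slot pixels numeric matrix of phase values (rows x cols).
#' @slot sourceId character scalar identifying the image's origin.
#' @export
setClass("QPIImage",
  representation(pixels = "matrix", sourceId = "character"),
  prototype(sourceId = NA_character_))

setValidity("QPIImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (!all(is.finite(p))) return("pixels contain non-finite values (NaN/Inf)")
  TRUE
})

#' NormalizedImage: 8-bit min-max normalized image
#'
#' Integer values in \[0, 255\] obtained by per-image min-max scaling with
#' round-half-up quantization; `normParams` records the observed (min, max)
#' of the source image so the scaling is auditable.
#'
#' @slot pixels numeric matrix with integral values in \[0, 255\].
#' @slot normParams numeric(2): observed min and max of the source image.
#' @export
setClass("NormalizedImage",
  representation(pixels = "matrix", normParams = "numeric"))

setValidity("NormalizedImage", function(object) {
  p <- object@pixels
  if (any(p < 0 | p > 255)) return("values must lie in [0, 255]")
  if (any(p != round(p))) return("values must be integral")
  if (length(object@normParams) != 2L) return("normParams must have length 2")
  if (object@normParams[1] > object@normParams[2])
    return("normParams min exceeds max")
  TRUE
})

#' BinaryMask: per-pixel lipid / non-lipid labels
#'
#' @slot pixels numeric matrix of 0 (non-lipid) / 1 (lipid).
#' @export
setClass("BinaryMask", representation(pixels = "matrix"))

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  if (!all(p %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' PadRecord: border bookkeeping for canvas padding
#'
#' Records how many zero rows/columns were added on each side to centre an
#' image on a square canvas, sufficient to invert the padding exactly.
#'
#' @slot left,right,top,bottom integer pixel counts (non-negative).
#' @slot canvas integer target side length.
#' @export
setClass("PadRecord",
  representation(left = "integer", right = "integer",
                 top = "integer", bottom = "integer", canvas = "integer"))

setValidity("PadRecord", function(object) {
  v <- c(object@left, object@right, object@top, object@bottom)
  if (any(v < 0L)) return("pad amounts must be non-negative")
  if (abs(object@left - object@right) > 1L) return("|left - right| must be <= 1")
  if (abs(object@top - object@bottom) > 1L) return("|top - bottom| must be <= 1")
  TRUE
})

#' FilterSpec: one parametrized image filter
#'
#' @slot id unique identifier within a bank.
#' @slot family filter family name (e.g. "gaussian", "median").
#' @slot params named list of family-specific scalars (sigma, window, quantile).
#' @export
setClass("FilterSpec",
  representation(id = "character", family = "character", params = "list"))

.filterFamilies <- c("identity", "gaussian", "difference_of_gaussians",
                     "laplacian_of_gaussian", "sobel_of_gaussian",
                     "gradient_magnitude", "structure_tensor_eig_large",
                     "structure_tensor_eig_small", "median",
                     "intensity_threshold")

setValidity("FilterSpec", function(object) {
  if (!object@family %in% .filterFamilies)
    return(sprintf("unknown filter family '%s'", object@family))
  p <- object@params
  if (!is.null(p$sigma) && any(unlist(p[grep("sigma", names(p))]) <= 0))
    return("sigma must be positive")
  if (!is.null(p$window) &&
      (p$window < 3 || p$window %% 2 != 1))
    return("window must be odd and >= 3")
  if (!is.null(p$quantile) && (p$quantile <= 0 || p$quantile >= 1))
    return("quantile must lie in (0, 1)")
  TRUE
})

#' FilterBank: an ordered set of filters defining the feature space
#'
#' @slot specs list of [FilterSpec-class] objects, ids unique.
#' @slot bankId character identifier used to guard feature provenance.
#' @export
setClass("FilterBank",
  representation(specs = "list", bankId = "character"))

setValidity("FilterBank", function(object) {
  ids <- vapply(object@specs, function(s) s@id, character(1))
  if (anyDuplicated(ids)) return("filter ids must be unique within a bank")
  TRUE
})

#' FeatureStack: per-pixel features for one image
#'
#' A (height, width, k) array; layer j holds filter j's response. The third
#' dimension is named with the filter ids.
#'
#' @slot values 3D numeric array (h, w, k).
#' @slot bankId provenance: id of the bank that produced the stack.
#' @export
setClass("FeatureStack",
  representation(values = "array", bankId = "character"))

setValidity("FeatureStack", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (!all(is.finite(object@values))) return("feature values must be finite")
  TRUE
})

#' PixelMatrix: flattened training matrix
#'
#' One row per pixel (image order, then row-major within each image), one
#' column per filter; binary labels aligned to rows.
#'
#' @slot data n x k numeric matrix, columns named with filter ids.
#' @slot labels integer vector of 0/1, length n.
#' @slot imageIndex integer vector mapping rows to source images.
#' @slot bankId feature provenance.
#' @export
setClass("PixelMatrix",
  representation(data = "matrix", labels = "integer",
                 imageIndex = "integer", bankId = "character"))

setValidity("PixelMatrix", function(object) {
  n <- nrow(object@data)
  if (length(object@labels) != n) return("labels length must equal row count")
  if (length(object@imageIndex) != n)
    return("imageIndex length must equal row count")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  TRUE
})

#' ClassicHyperparams: hyperparameters for the classical backends
#'
#' Defaults reproduce the published settings: RF 100 trees; XGB 100 rounds,
#' max depth 4, subsample 0.5; SVM polynomial kernel degree 3 with the
#' "scale" gamma heuristic; MLP hidden layers (50, 25) with ReLU and Adam;
#' LDA via singular value decomposition. Thread counts are advisory caps.
#'
#' @slot method one of "RF", "XGB", "SVM", "MLP", "LDA".
#' @slot params named list of backend settings.
#' @export
setClass("ClassicHyperparams",
  representation(method = "character", params = "list"))

setValidity("ClassicHyperparams", function(object) {
  if (!object@method %in% c("RF", "XGB", "SVM", "MLP", "LDA"))
    return("method must be one of RF, XGB, SVM, MLP, LDA")
  cnt <- unlist(object@params[names(object@params) %in%
    c("n_estimators", "n_threads", "max_depth", "max_iterations",
      "n_iter_no_change", "degree", "cache_mb")])
  if (any(cnt <= 0)) return("count-valued hyperparameters must be positive")
  TRUE
})

#' TrainedPixelClassifier: a fitted classical per-pixel model
#'
#' @slot method backend id.
#' @slot hyperparams the [ClassicHyperparams-class] used.
#' @slot bankId feature provenance; classification input must match.
#' @slot fit backend-specific fitted object.
#' @slot trainingSummary list: n rows, class balance, seed, warnings.
#' @export
setClass("TrainedPixelClassifier",
  representation(method = "character", hyperparams = "ClassicHyperparams",
                 bankId = "character", fit = "ANY",
                 trainingSummary = "list"))

#' ConfusionCounts: pixelwise confusion-matrix tallies
#'
#' @slot tp,tn,fp,fn non-negative counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric",
                 fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
  TRUE
})

#' MetricsReport: the six segmentation scores for one comparison
#'
#' Scores with a zero denominator are NaN and listed in `flags` as
#' uninterpretable; they are excluded from cross-fold averaging.
#'
#' @slot scores named numeric: accuracy, balanced_accuracy, precision,
#'   recall, dice, jaccard (each in \[0,1\] or NaN).
#' @slot counts the underlying [ConfusionCounts-class].
#' @slot flags character vector naming uninterpretable scores.
#' @export
setClass("MetricsReport",
  representation(scores = "numeric", counts = "ConfusionCounts",
                 flags = "character"))

#' RocCurve: receiver operating characteristic sweep
#'
#' @slot fpr,tpr coordinates from (0,0) to (1,1), monotone non-decreasing.
#' @slot auc area under the curve (probability a random positive outranks a
#'   random negative; ties count 1/2).
#' @export
setClass("RocCurve",
  representation(fpr = "numeric", tpr = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (length(object@fpr) != length(object@tpr)) return("fpr/tpr length mismatch")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    return("ROC points must be monotone non-decreasing")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  TRUE
})

#' SceneSpec: generative description of a synthetic QPI scene
#'
#' One elliptical cell of intermediate phase on a dark background with
#' 0-6 bright circular droplets inside; additive Gaussian noise and optional
#' blur. Phase ordering background < cell < droplet is enforced, mirroring
#' the refractive-index ordering of real QPI cell images.
#'
#' @slot canvas side length in pixels.
#' @slot cell list: centerJitter (fraction of canvas), semiAxes (range, px),
#'   phase (cytosol phase level).
#' @slot droplets list: count (integer range), radius (range, px),
#'   phase (droplet phase level), nonOverlap flag.
#' @slot background background phase level (default 0).
#' @slot noise list: sd (additive Gaussian), blur (Gaussian sd, 0 = none).
#' @export
setClass("SceneSpec",
  representation(canvas = "integer", cell = "list", droplets = "list",
                 background = "numeric", noise = "list"))

setValidity("SceneSpec", function(object) {
  if (object@canvas < 8L) return("canvas too small")
  if (!(object@background < object@cell$phase &&
        object@cell$phase < object@droplets$phase))
    return("phase ordering must satisfy background < cell < droplet")
  if (min(object@droplets$radius) < 1) return("droplet radii must be >= 1 px")
  if (min(object@droplets$count) < 0) return("droplet count must be >= 0")
  TRUE
})

#' SyntheticPair: a generated image with its exact ground-truth mask
#'
#' @slot image the noisy [QPIImage-class].
#' @slot mask [BinaryMask-class]; positives are exactly the rasterized disks.
#' @slot provenance list: the SceneSpec, seed, and draw record.
#' @export
setClass("SyntheticPair",
  representation(image = "QPIImage", mask = "BinaryMask",
                 provenance = "list"))

#' UNetConfig: architecture configuration for the U-Net dialect
#'
#' @slot canvas input side length (divisible by 16).
#' @slot inChannels input channels (1 for grayscale phase images).
#' @slot encoderWidths filter counts of the four encoder blocks.
#' @slot bottleneckWidth filter count at the bottleneck.
#' @slot dropoutRate dropout probability at the two deepest blocks.
#' @slot threshold probability cutoff turning the sigmoid map into a mask.
#' @export
setClass("UNetConfig",
  representation(canvas = "integer", inChannels = "integer",
                 encoderWidths = "integer", bottleneckWidth = "integer",
                 dropoutRate = "numeric", threshold = "numeric"))

setValidity("UNetConfig", function(object) {
  if (object@canvas %% 16L != 0L) return("canvas must be divisible by 16")
  if (length(object@encoderWidths) != 4L) return("need 4 encoder widths")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0,1)")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropout must lie in [0,1)")
  TRUE
})

#' UNetModel: a built (possibly trained) network
#'
#' @slot layers named list of convolution layers (weights, biases, geometry).
#' @slot config the [UNetConfig-class] it was built from.
#' @slot seed integer seed used for weight initialization.
#' @export
setClass("UNetModel",
  representation(layers = "list", config = "UNetConfig", seed = "integer"))

#' TrainRecord: training history of a U-Net run
#'
#' @slot epochs number of epochs run.
#' @slot loss per-epoch mean binary cross-entropy.
#' @slot batchSize minibatch size.
#' @slot seed RNG seed.
#' @slot optimizer list: name, learning rate, Adam moments settings.
#' @export
setClass("TrainRecord",
  representation(epochs = "integer", loss = "numeric",
                 batchSize = "integer", seed = "integer",
                 optimizer = "list"))

setValidity("TrainRecord", function(object) {
  if (length(object@loss) != object@epochs)
    return("loss history length must equal epochs run")
  if (any(object@loss < 0)) return("loss values must be non-negative")
  TRUE
})

#' ExperimentConfig: settings for the evaluation protocols
#'
#' @slot kFolds fold count for cross-validation (unshuffled, default 5).
#' @slot trainingSizes training-set sizes for the sweep.
#' @slot methods subset of RF, XGB, SVM, MLP, LDA, CNN.
#' @slot seed base RNG seed.
#' @slot epochs CNN training epochs.
#' @slot bank the [FilterBank-class] used for classical methods.
#' @slot unet the [UNetConfig-class] used for the CNN method.
#' @slot numThreads advisory thread cap for backends that parallelize.
#' @export
setClass("ExperimentConfig",
  representation(kFolds = "integer", trainingSizes = "integer",
                 methods = "character", seed = "integer",
                 epochs = "integer", bank = "FilterBank",
                 unet = "UNetConfig", numThreads = "integer"))

setValidity("ExperimentConfig", function(object) {
  if (object@kFolds < 2L) return("kFolds must be >= 2")
  if (any(object@trainingSizes < 1L)) return("training sizes must be positive")
  bad <- setdiff(object@methods, c("RF", "XGB", "SVM", "MLP", "LDA", "CNN"))
  if (length(bad)) return(sprintf("unknown methods: %s", paste(bad, collapse = ", ")))
  TRUE
})

#' CVResult: cross-validation outcome for one method
#'
#' @slot method method id.
#' @slot foldScores k x 6 matrix of per-fold scores (per-image means).
#' @slot means per-metric means across folds, NaN folds excluded.
#' @slot exclusions per-metric count of folds excluded as uninterpretable.
#' @slot pooled list of per-fold [MetricsReport-class] built from pooled
#'   pixel counts across the fold's validation images.
#' @export
setClass("CVResult",
  representation(method = "character", foldScores = "matrix",
                 means = "numeric", exclusions = "numeric",
                 pooled = "list"))
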