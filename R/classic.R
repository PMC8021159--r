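# The five classical per-pixel classifiers behind one uniform surface.
#
# Backends: ranger (random forest), xgboost (gradient boosting),
# e1071/libsvm (polynomial SVM), the package's own dense-network engine
# (multilayer perceptron), and MASS::lda. Hyperparameter defaults follow
# the published table; thread counts are treated as advisory caps (set
# `options(dropseg.max_threads = n)` to allow more than one thread).

.classicDefaults <- list(
  RF  = list(n_estimators = 100L, n_threads = 25L),
  XGB = list(n_estimators = 100L, n_threads = 25L, max_depth = 4L,
             subsample = 0.5),
  SVM = list(kernel = "polynomial", degree = 3L, gamma = "scale",
             max_iterations = 1000L, cache_mb = 5000L),
  MLP = list(hidden_layers = c(50L, 25L), activation = "relu",
             solver = "adam", max_iterations = 1000L,
             n_iter_no_change = 50L),
  LDA = list(solver = "svd"))

#' Hyperparameters for a classical backend
#'
#' Returns the published defaults for `method`, with any named overrides
#' applied. Unknown settings are rejected.
#'
#' @param method one of "RF", "XGB", "SVM", "MLP", "LDA".
#' @param ... named overrides of the method's settings.
#' @return a [ClassicHyperparams-class].
#' @export
classicHyperparams <- function(method = c("RF", "XGB", "SVM", "MLP", "LDA"),
                               ...) {
  method <- match.arg(method)
  params <- .classicDefaults[[method]]
  over <- list(...)
  bad <- setdiff(names(over), names(params))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", method, ": ",
         paste(bad, collapse = ", "))
  params[names(over)] <- over
  new("ClassicHyperparams", method = method, params = params)
}

.effectiveThreads <- function(requested) {
  cap <- getOption("dropseg.max_threads", 1L)
  max(1L, min(as.integer(requested), as.integer(cap)))
}

#' Train a classical per-pixel classifier
#'
#' @param pm a [PixelMatrix-class] with both classes present.
#' @param hp a [ClassicHyperparams-class], or a method name (defaults used).
#' @param seed integer seed; all stochastic backends are seeded so training
#'   is reproducible.
#' @return a [TrainedPixelClassifier-class].
#' @export
trainPixelClassifier <- function(pm, hp = "RF", seed = 0L) {
  stopifnot(is(pm, "PixelMatrix"))
  if (is.character(hp)) hp <- classicHyperparams(hp)
  X <- pm@data
  y <- pm@labels
  if (nrow(X) < 1L) stop("empty training matrix")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both lipid and ",
         "non-lipid pixels are required")
  p <- hp@params
  set.seed(seed)
  warn <- character(0)
  fit <- switch(hp@method,
    RF = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)),
      num.trees = p$n_estimators,
      num.threads = .effectiveThreads(p$n_threads),
      seed = seed, probability = TRUE, importance = "impurity",
      verbose = FALSE),
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(data = X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth, subsample = p$subsample,
                      nthread = .effectiveThreads(p$n_threads),
                      seed = seed),
        data = dtrain, nrounds = p$n_estimators, verbose = 0)
    },
    SVM = {
      gamma <- if (identical(p$gamma, "scale"))
        1 / (ncol(X) * stats::var(as.vector(X))) else p$gamma
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                 kernel = "polynomial", degree = p$degree, gamma = gamma,
                 cachesize = p$cache_mb, scale = FALSE)
    },
    MLP = {
      f <- .mlpFit(X, y, hidden = p$hidden_layers,
                   maxIter = p$max_iterations,
                   patience = p$n_iter_no_change, seed = seed)
      if (!f$converged) {
        warn <- c(warn, "MLP reached max_iterations without convergence")
        warning(warn[length(warn)], call. = FALSE)
      }
      f
    },
    LDA = {
      # mirror the svd solver's tolerance for degenerate directions:
      # drop features constant within both groups before the fit
      keep <- which(apply(X[y == 0, , drop = FALSE], 2, stats::var) +
                    apply(X[y == 1, , drop = FALSE], 2, stats::var) > 1e-12)
      if (length(keep) == 0L) stop("all features are constant within groups")
      list(lda = suppressWarnings(
             MASS::lda(x = X[, keep, drop = FALSE],
                       grouping = factor(y, levels = c(0, 1)))),
           keep = keep)
    })
  new("TrainedPixelClassifier",
      method = hp@method, hyperparams = hp, bankId = pm@bankId, fit = fit,
      trainingSummary = list(n = nrow(X),
                             positive_fraction = mean(y),
                             seed = as.integer(seed),
                             feature_names = colnames(X),
                             warnings = warn))
}

# Per-backend score (probability-like, class 1) for a plain feature matrix.
.classicScores <- function(model, X) {
  switch(model@method,
    RF = {
      pr <- predict(model@fit, data = X,
                    num.threads = .effectiveThreads(
                      model@hyperparams@params$n_threads))$predictions
      pr[, "1"]
    },
    XGB = predict(model@fit, xgboost::xgb.DMatrix(X)),
    SVM = {
      pv <- predict(model@fit, newdata = X, decision.values = TRUE)
      dv <- attr(pv, "decision.values")
      # libsvm orients the decision value toward the first level of the
      # column name; flip so positive always favours class "1"
      s <- if (startsWith(colnames(dv)[1], "1/")) dv[, 1] else -dv[, 1]
      stats::plogis(s)
    },
    MLP = .mlpPredict(model@fit, X),
    LDA = predict(model@fit$lda,
                  newdata = X[, model@fit$keep, drop = FALSE])$posterior[, "1"],
    stop("unknown method: ", model@method))
}

# The backend's native decision rule on the same matrix.
.classicClasses <- function(model, X, scoreCache = NULL) {
  if (model@method == "SVM")
    return(as.integer(as.character(predict(model@fit, newdata = X))))
  s <- if (is.null(scoreCache)) .classicScores(model, X) else scoreCache
  as.integer(s >= 0.5)
}

#' Classify every pixel of a feature stack
#'
#' Flattens the stack, scores each pixel with the trained backend, and
#' reshapes both the score map and the binary decision back to image
#' dimensions. The stack must come from the same filter bank the model was
#' trained on.
#'
#' @param model a [TrainedPixelClassifier-class].
#' @param stack a [FeatureStack-class] with matching `bankId`.
#' @return list with `scoreMap` (matrix in \[0,1\]) and `mask`
#'   ([BinaryMask-class]), both with the stack's spatial dimensions.
#' @export
classifyPixels <- function(model, stack) {
  stopifnot(is(stack, "FeatureStack"))
  if (!identical(model@bankId, stack@bankId))
    stop(sprintf("feature bank mismatch: model trained on '%s', stack from '%s'",
                 model@bankId, stack@bankId))
  d <- dim(stack@values)
  X <- .flattenStack(stack@values)
  s <- .classicScores(model, X)
  cls <- .classicClasses(model, X, scoreCache = s)
  scoreMap <- t(matrix(s, nrow = d[2], ncol = d[1]))
  mask <- t(matrix(as.numeric(cls), nrow = d[2], ncol = d[1]))
  list(scoreMap = scoreMap, mask = binaryMask(mask))
}

#' Feature importances of a tree-ensemble model
#'
#' Impurity importance for random forests, gain for gradient boosting;
#' normalized to sum to 1 and sorted descending. Only tree ensembles
#' expose importances.
#'
#' @param model a [TrainedPixelClassifier-class] with method RF or XGB.
#' @return data.frame with columns `id` (filter id) and `importance`.
#' @export
featureImportances <- function(model) {
  if (!model@method %in% c("RF", "XGB"))
    stop("feature importances are unsupported for method ", model@method,
         "; only tree ensembles (RF, XGB) expose them")
  feats <- model@trainingSummary$feature_names
  imp <- setNames(rep(0, length(feats)), feats)
  if (model@method == "RF") {
    vi <- model@fit$variable.importance
    imp[names(vi)] <- pmax(vi, 0)
  } else {
    tab <- xgboost::xgb.importance(model = model@fit)
    imp[tab$Feature] <- tab$Gain
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(id = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

.modelFormatVersion <- 1L

#' Save a trained classifier to a single-file blob
#'
#' The blob carries a header (format version, method, bank id) so loads can
#' be validated; gradient-boosting models are stored in their portable raw
#' form.
#'
#' @param model a [TrainedPixelClassifier-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveModel <- function(model, path) {
  payload <- if (model@method == "XGB")
    xgboost::xgb.save.raw(model@fit) else model@fit
  blob <- list(format_version = .modelFormatVersion,
               method = model@method,
               bank_id = model@bankId,
               hyperparams = model@hyperparams@params,
               training_summary = model@trainingSummary,
               payload = payload)
  saveRDS(blob, path)
  invisible(path)
}

#' Load a classifier saved with [saveModel()]
#'
#' @param path path to the blob.
#' @param expectedBankId optional bank id to validate against; a mismatch
#'   is an error.
#' @return a [TrainedPixelClassifier-class] with identical classification
#'   behaviour.
#' @export
loadModel <- function(path, expectedBankId = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  blob <- tryCatch(readRDS(path),
                   error = function(e) stop("corrupted model file: ", path))
  if (!is.list(blob) || is.null(blob$format_version) ||
      blob$format_version != .modelFormatVersion)
    stop("unrecognized model format in ", path)
  if (!is.null(expectedBankId) && !identical(blob$bank_id, expectedBankId))
    stop(sprintf("model bank '%s' does not match expected bank '%s'",
                 blob$bank_id, expectedBankId))
  fit <- if (blob$method == "XGB") xgboost::xgb.load.raw(blob$payload)
         else blob$payload
  hp <- new("ClassicHyperparams", method = blob$method,
            params = blob$hyperparams)
  new("TrainedPixelClassifier", method = blob$method, hyperparams = hp,
      bankId = blob$bank_id, fit = fit,
      trainingSummary = blob$training_summary)
}
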