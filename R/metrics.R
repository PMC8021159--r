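# Confusion-matrix accounting, the six segmentation scores, and ROC/AUC.

#' Pixelwise confusion counts between a prediction and the truth
#'
#' @param pred predicted [BinaryMask-class] (or 0/1 matrix).
#' @param truth ground-truth [BinaryMask-class] (or 0/1 matrix), same
#'   dimensions.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  p <- if (is(pred, "BinaryMask")) pred@pixels else pred
  t <- if (is(truth, "BinaryMask")) truth@pixels else truth
  if (!identical(dim(p), dim(t)))
    stop(sprintf("dimension mismatch: prediction %dx%d vs truth %dx%d",
                 nrow(p), ncol(p), nrow(t), ncol(t)))
  new("ConfusionCounts",
      tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
      fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1))
}

.metricNames <- c("accuracy", "balanced_accuracy", "precision", "recall",
                  "dice", "jaccard")

#' Compute the six segmentation scores from confusion counts
#'
#' Accuracy = (TP+TN)/total; balanced accuracy = (TP/P + TN/N)/2;
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' Dice/F1 = 2TP/(2TP+FP+FN); Jaccard = TP/(TP+FP+FN).
#' Any score with a zero denominator is NaN and flagged as
#' uninterpretable (e.g. precision when nothing is predicted positive);
#' averaging utilities exclude flagged values and report the exclusions.
#'
#' @param cc a [ConfusionCounts-class] with a positive total.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  tp <- cc@tp; tn <- cc@tn; fp <- cc@fp; fn <- cc@fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("cannot score an empty comparison (zero pixels)")
  P <- tp + fn; N <- tn + fp
  safe <- function(num, den) if (den == 0) NaN else num / den
  s <- c(accuracy = (tp + tn) / total,
         balanced_accuracy = if (P == 0 || N == 0) NaN
           else (tp / P + tn / N) / 2,
         precision = safe(tp, tp + fp),
         recall = safe(tp, P),
         dice = safe(2 * tp, 2 * tp + fp + fn),
         jaccard = safe(tp, tp + fp + fn))
  new("MetricsReport", scores = s, counts = cc,
      flags = names(s)[is.nan(s)])
}

#' Compare two masks and report the six scores
#'
#' Convenience wrapper around [confusionCounts()] and [computeMetrics()].
#'
#' @inheritParams confusionCounts
#' @return a [MetricsReport-class].
#' @export
scoreMasks <- function(pred, truth) computeMetrics(confusionCounts(pred, truth))

#' ROC curve and AUC from per-pixel scores
#'
#' Sweeps all distinct score thresholds from high to low; the AUC equals
#' the probability that a randomly chosen positive pixel outranks a
#' randomly chosen negative one, with ties counting one half
#' (Mann-Whitney convention).
#'
#' @param scoreValues numeric vector of classifier scores (higher = more
#'   lipid-like).
#' @param labels 0/1 vector of true labels; both classes must be present.
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(scoreValues, labels) {
  labels <- as.numeric(labels)
  if (length(scoreValues) != length(labels))
    stop("scores and labels must have equal length")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("ROC requires at least one positive and one negative label")
  ord <- order(scoreValues, decreasing = TRUE)
  s <- scoreValues[ord]; y <- labels[ord]
  cumTP <- cumsum(y == 1); cumFP <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie block
  tpr <- c(0, cumTP[last] / npos)
  fpr <- c(0, cumFP[last] / nneg)
  r <- rank(scoreValues)                   # average ranks: ties count 1/2
  aucVal <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  new("RocCurve", fpr = fpr, tpr = tpr, auc = aucVal)
}

#' Average metric reports, excluding uninterpretable scores
#'
#' @param reports list of [MetricsReport-class].
#' @return list with `means` (named numeric), `excluded` (per-metric count
#'   of NaN values dropped), and `n` (number of reports).
#' @export
averageMetrics <- function(reports) {
  m <- do.call(rbind, lapply(reports, scores))
  means <- apply(m, 2, function(col) mean(col[!is.nan(col)]))
  list(means = means, excluded = colSums(is.nan(m)), n = length(reports))
}

#' Write metric reports as a CSV table
#'
#' One row per report: the six scores, the four confusion cells, and a
#' flags column naming uninterpretable scores.
#'
#' @param reports list of [MetricsReport-class].
#' @param path output CSV path.
#' @param ids optional row identifiers.
#' @return the data.frame written, invisibly.
#' @export
writeMetricsCsv <- function(reports, path, ids = seq_along(reports)) {
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(id = ids[i], t(scores(r)),
               tp = r@counts@tp, tn = r@counts@tn,
               fp = r@counts@fp, fn = r@counts@fn,
               flags = paste(r@flags, collapse = ";"))
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
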