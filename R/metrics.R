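# Segmentation and classification metrics. The overlap scores use a smooth
# constant (default 1e-32) in numerator and denominator so that empty-vs-empty
# comparisons are well defined; the Hausdorff distance is directed by default.

#' Flagged undefined metric value
#'
#' Metrics that hit a 0/0 (e.g. precision with no positive predictions) return
#' `NaN` carrying the attribute `undefined = TRUE` rather than a silent zero.
#'
#' @param x a metric value.
#' @return `TRUE` if `x` is a flagged undefined value.
#' @export
is_undefined <- function(x) isTRUE(attr(x, "undefined"))

undefined_value <- function() structure(NaN, undefined = TRUE)

check_same_shape <- function(pred, targ) {
  if (!identical(dim2(pred), dim2(targ)))
    stopf("pred and targ shapes differ: [%s] vs [%s]",
          paste(dim2(pred), collapse = ","), paste(dim2(targ), collapse = ","))
}
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Dice similarity coefficient
#'
#' `(2 * inter + smooth) / (sum(pred) + sum(targ) + smooth)` where `inter` is
#' the sum of the elementwise product. `pred` may be a probability raster
#' (soft Dice) or binary; `targ` must be binary.
#'
#' @param pred prediction raster (binary or probabilities in \[0, 1\]).
#' @param targ binary reference raster of the same shape.
#' @param smooth stabilizing constant, default `1e-32`.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(pred, targ, smooth = 1e-32) {
  check_same_shape(pred, targ)
  inter <- sum(pred * targ)
  (2 * inter + smooth) / (sum(pred) + sum(targ) + smooth)
}

#' Jaccard index (intersection over union)
#'
#' `(inter + smooth) / (sum(pred) + sum(targ) - inter + smooth)`.
#'
#' @inheritParams dice
#' @return Jaccard score in \[0, 1\].
#' @export
jaccard <- function(pred, targ, smooth = 1e-32) {
  check_same_shape(pred, targ)
  inter <- sum(pred * targ)
  (inter + smooth) / (sum(pred) + sum(targ) - inter + smooth)
}

#' Convert a binary mask to an n x 2 matrix of (row, col) foreground coordinates
#'
#' @param mask binary matrix.
#' @return integer matrix with one row per foreground pixel.
#' @export
mask_to_points <- function(mask) {
  which(mask == 1, arr.ind = TRUE)
}

#' Hausdorff distance between two point sets
#'
#' Directed by default: `max_{a in A} min_{b in B} d(a, b)` with Euclidean
#' `d`. With `symmetric = TRUE` returns `max(H(A,B), H(B,A))`, the convention
#' most segmentation papers use.
#'
#' @param A,B non-empty numeric matrices of coordinates (points in rows).
#' @param symmetric return the symmetrized distance? Default `FALSE`.
#' @return distance in pixel units.
#' @export
hausdorff <- function(A, B, symmetric = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stopf("hausdorff requires non-empty point sets")
  h <- function(P, Q) {
    # squared distances via the expansion |p|^2 + |q|^2 - 2 p.q
    pq <- tcrossprod(P, Q)
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * pq
    max(sqrt(pmax(apply(d2, 1L, min), 0)))
  }
  if (symmetric) max(h(A, B), h(B, A)) else h(A, B)
}

#' 2x2 confusion matrix and derived rates
#'
#' Counts agreement between predicted and true labels for a designated
#' positive class. Rates that involve division by zero are returned as flagged
#' undefined values (see [is_undefined()]).
#'
#' @param pred predicted labels (character/factor vector).
#' @param truth true labels, same length.
#' @param positive the label treated as the positive class.
#' @return object of class `confusion2` with fields `tp, fp, fn, tn`,
#'   `accuracy`, `precision`, `recall` (= sensitivity), `specificity`.
#' @export
confusion <- function(pred, truth, positive) {
  if (length(pred) != length(truth))
    stopf("pred and truth lengths differ (%d vs %d)", length(pred), length(truth))
  pp <- pred == positive; tp_ <- truth == positive
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_)
  fn <- sum(!pp & tp_); tn <- sum(!pp & !tp_)
  confusion_from_counts(tp, fp, fn, tn, positive)
}

#' Build a `confusion2` object from the four counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param positive label of the positive class (metadata only).
#' @return `confusion2` object; see [confusion()].
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, positive = "positive") {
  total <- tp + fp + fn + tn
  if (total <= 0) stopf("confusion matrix is empty")
  rate <- function(num, den) if (den == 0) undefined_value() else num / den
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, total = total, positive = positive,
    accuracy = (tp + tn) / total,
    precision = rate(tp, tp + fp),
    recall = rate(tp, tp + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp)
  ), class = "confusion2")
}

#' @export
print.confusion2 <- function(x, ...) {
  cat(sprintf("confusion2 (positive = %s)\n", x$positive))
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d  (n=%d)\n", x$tp, x$fp, x$fn, x$tn, x$total))
  cat(sprintf("  accuracy=%.4f precision=%.4f recall=%.4f specificity=%.4f\n",
              x$accuracy, x$precision, x$recall, x$specificity))
  invisible(x)
}

#' Rebuild a confusion matrix from class sizes and per-class recalls
#'
#' Useful for reconstructing a test-set contingency table from published
#' per-class recalls: `tp = round(recall_pos * n_pos)` (round half up),
#' `tn = round(recall_neg * n_neg)`, off-diagonals by complement.
#'
#' @param n_positive,n_negative class sizes (>= 1).
#' @param recall_positive,recall_negative per-class recalls in \[0, 1\].
#' @param positive positive-class label.
#' @return `confusion2` object.
#' @export
confusion_from_rates <- function(n_positive, n_negative,
                                 recall_positive, recall_negative,
                                 positive = "positive") {
  stopifnot(n_positive >= 1, n_negative >= 1,
            recall_positive >= 0, recall_positive <= 1,
            recall_negative >= 0, recall_negative <= 1)
  tp <- round_half_up(recall_positive * n_positive)
  tn <- round_half_up(recall_negative * n_negative)
  confusion_from_counts(tp, n_negative - tn, n_positive - tp, tn, positive)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; flagged undefined when both are zero.
#'
#' @param precision,recall values in \[0, 1\].
#' @return F1 score.
#' @export
f1 <- function(precision, recall) {
  if (is.nan(precision) || is.nan(recall) ||
      (precision == 0 && recall == 0)) return(undefined_value())
  2 * precision * recall / (precision + recall)
}

#' Youden's J index
#'
#' `sensitivity + specificity - 1`.
#'
#' @param sensitivity,specificity values in \[0, 1\].
#' @return index in \[-1, 1\].
#' @export
youden <- function(sensitivity, specificity) sensitivity + specificity - 1

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' `kappa = (p0 - pe) / (1 - pe)` with `p0` the observed accuracy and `pe`
#' the chance agreement: the sum over classes of (actual count x predicted
#' count) divided by the squared total.
#'
#' @param cm a `confusion2` object.
#' @return kappa in \[-1, 1\]; flagged undefined if `pe == 1`.
#' @export
kappa_score <- function(cm) {
  stopifnot(inherits(cm, "confusion2"))
  n <- cm$total
  p0 <- cm$accuracy
  actual_pos <- cm$tp + cm$fn; actual_neg <- cm$fp + cm$tn
  pred_pos <- cm$tp + cm$fp; pred_neg <- cm$fn + cm$tn
  pe <- (actual_pos * pred_pos + actual_neg * pred_neg) / n^2
  if (pe == 1) return(undefined_value())
  (p0 - pe) / (1 - pe)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds, returns (FPR, TPR) points and the trapezoidal
#' area. Tied scores are grouped, which makes the area identical to the
#' normalized Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores numeric scores; larger means more likely positive.
#' @param labels true labels.
#' @param positive label of the positive class.
#' @return list with `auc` and a data.frame `roc` of `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels, positive) {
  y <- labels == positive
  if (!any(y) || all(y)) stopf("roc_auc needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  # keep the last index of each tied-score group
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Full classification metric report
#'
#' Computes accuracy, per-class precision/recall/F1, Youden index, kappa and
#' (when scores are supplied) AUC with the ROC points, in the JSON-ready
#' layout used by the pipeline.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param scores optional numeric score of the positive class for ROC/AUC.
#' @param positive positive-class label (also the ROC score class).
#' @return nested list; see details.
#' @export
classification_report <- function(pred, truth, scores = NULL,
                                  positive = "malignant") {
  classes <- sort(unique(c(truth, pred)))
  per_class <- lapply(classes, function(cl) {
    cm <- confusion(pred, truth, positive = cl)
    list(precision = as.numeric(cm$precision),
         recall = as.numeric(cm$recall),
         f1 = as.numeric(f1(cm$precision, cm$recall)))
  })
  names(per_class) <- classes
  cmp <- confusion(pred, truth, positive = positive)
  rep <- list(
    accuracy = cmp$accuracy,
    per_class = per_class,
    youden = youden(cmp$sensitivity, cmp$specificity),
    kappa = as.numeric(kappa_score(cmp))
  )
  if (!is.null(scores)) {
    r <- roc_auc(scores, truth, positive)
    rep$auc <- r$auc
    rep$roc <- r$roc
  }
  rep
}

#' Segmentation metric report for a predicted/reference mask pair
#'
#' @param pred_mask,true_mask binary masks of identical shape.
#' @param symmetric_hausdorff symmetrize the Hausdorff distance? Default FALSE
#'   (directed).
#' @return list with `dice`, `jaccard`, `hausdorff` (NA when either mask is
#'   empty).
#' @export
segmentation_report <- function(pred_mask, true_mask, symmetric_hausdorff = FALSE) {
  hd <- if (sum(pred_mask) > 0 && sum(true_mask) > 0)
    hausdorff(mask_to_points(pred_mask), mask_to_points(true_mask),
              symmetric = symmetric_hausdorff)
  else NA_real_
  list(dice = dice(pred_mask, true_mask),
       jaccard = jaccard(pred_mask, true_mask),
       hausdorff = hd)
}

#' Write a metric report to JSON (full precision)
#'
#' @param report list, e.g. from [classification_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  # I(17) significant digits guarantees doubles survive the round trip
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read a metric report written by [write_report()]
#'
#' @param path JSON path.
#' @return list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
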