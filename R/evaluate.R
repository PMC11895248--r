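# Pixel-level segmentation metrics: confusion counts, accuracy, a
# threshold-swept ROC with trapezoidal AUC, Dice and IoU.  Micro
# aggregation (global pixel sums) is the primary surface; per-image values
# are reported alongside.

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1)))
    stop(name, " must be binary (0/1)")
}

#' Pixel-level confusion counts
#'
#' @param pred,truth binary masks of equal shape (0/1).
#' @return list with `TP`, `TN`, `FP`, `FN` pixel counts.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth shapes differ")
  check_binary(pred, "pred"); check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Pixel accuracy from confusion counts
#'
#' `(TP + TN) / (TP + FP + FN + TN)`.  Note that under heavy class
#' imbalance this is dominated by background pixels; Dice and IoU are the
#' primary quality measures for tiny lesions.
#'
#' @param counts list from [confusion_counts()].
#' @return fraction in `[0, 1]`.
#' @export
pixel_accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("empty input: no pixels to evaluate")
  (counts$TP + counts$TN) / total
}

#' Threshold-swept ROC curve and AUC
#'
#' Sweeps binarisation thresholds over the probability map, computes
#' TPR = TP/(TP+FN) and FPR = FP/(FP+TN) at each, anchors the curve at
#' (0,0) and (1,1), and integrates trapezoidally.  The threshold grid is
#' `n_thresholds` evenly spaced values joined with the empirical score set
#' when the latter is small, so the curve is exact for quantised maps.
#'
#' @param prob numeric array of scores/probabilities.
#' @param truth binary mask of equal shape containing both classes.
#' @param n_thresholds number of evenly spaced thresholds.
#' @return list with `fpr`, `tpr` (per threshold, decreasing in
#'   threshold), `thresholds`, and `auc`.
#' @export
roc_auc <- function(prob, truth, n_thresholds = 256L) {
  if (length(prob) != length(truth)) stop("prob and truth shapes differ")
  check_binary(truth, "truth")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0)
    stop("ROC undefined: truth contains a single class")
  uq <- unique(as.vector(prob))
  grid <- seq(min(prob), max(prob), length.out = n_thresholds)
  if (length(uq) <= 1e4) grid <- c(grid, uq)
  thr <- sort(unique(grid), decreasing = TRUE)
  # pred = prob >= t; count positives/negatives with score >= t via
  # cumulative tallies over the threshold bins
  pos_scores <- prob[truth == 1]
  neg_scores <- prob[truth == 0]
  # findInterval on -scores against -thr gives counts >= t quickly
  tp <- vapply(thr, function(t) sum(pos_scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(neg_scores >= t), numeric(1))
  tpr <- tp / npos
  fpr <- fp / nneg
  fx <- c(0, fpr, 1)
  tx <- c(0, tpr, 1)
  ord <- order(fx, tx)
  fx <- fx[ord]; tx <- tx[ord]
  auc <- sum(diff(fx) * (head(tx, -1) + tail(tx, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc)
}

#' Dice similarity coefficient
#'
#' `2 |G intersect S| / (|G| + |S|)`, computed in the equivalent overlap
#' form `2 TP / (2 TP + FP + FN)`; defined as 1 when both masks are empty.
#'
#' @param pred,truth binary masks of equal shape.
#' @return value in `[0, 1]`.
#' @export
dice_coef <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth shapes differ")
  inter <- sum(pred == 1 & truth == 1)
  tot <- sum(pred == 1) + sum(truth == 1)
  if (tot == 0) return(1)
  2 * inter / tot
}

#' Intersection over union (Jaccard index)
#'
#' `|G intersect S| / |G union S|`; defined as 1 when both masks are
#' empty.  Related to Dice by `dice = 2 iou / (1 + iou)`.
#'
#' @inheritParams dice_coef
#' @return value in `[0, 1]`.
#' @export
iou_coef <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth shapes differ")
  inter <- sum(pred == 1 & truth == 1)
  uni <- sum(pred == 1 | truth == 1)
  if (uni == 0) return(1)
  inter / uni
}

#' Evaluate predictions over a test set
#'
#' Micro-aggregates confusion counts over all pixels of all probability
#' maps, reports accuracy, Dice and IoU at the binarisation threshold plus
#' ROC/AUC from the raw probabilities, and a per-image breakdown.
#'
#' @param probs list of probability maps (or one array).
#' @param truths list of binary masks aligned with `probs`.
#' @param threshold binarisation threshold.
#' @param n_thresholds ROC sweep resolution.
#' @return a `masegnet_metrics` list: `counts`, `accuracy`, `dice`, `iou`,
#'   `auc`, `roc`, `threshold`, `per_image` (data.frame).
#' @export
evaluate_predictions <- function(probs, truths, threshold = 0.5,
                                 n_thresholds = 256L) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(truths)) truths <- list(truths)
  if (length(probs) != length(truths)) stop("probs/truths misaligned")
  if (length(probs) == 0) stop("empty evaluation set")
  all_p <- unlist(probs, use.names = FALSE)
  all_t <- unlist(truths, use.names = FALSE)
  pred <- (all_p > threshold) * 1
  counts <- confusion_counts(pred, all_t)
  per <- do.call(rbind, lapply(seq_along(probs), function(i) {
    pi <- (probs[[i]] > threshold) * 1
    data.frame(image = i,
               dice = dice_coef(pi, truths[[i]]),
               iou = iou_coef(pi, truths[[i]]),
               accuracy = mean(pi == truths[[i]]),
               lesion_pixels = sum(truths[[i]] == 1))
  }))
  roc <- if (sum(all_t == 1) > 0 && sum(all_t == 0) > 0)
    roc_auc(all_p, all_t, n_thresholds) else NULL
  structure(list(counts = counts,
                 accuracy = pixel_accuracy(counts),
                 dice = dice_coef(pred, all_t),
                 iou = iou_coef(pred, all_t),
                 auc = if (is.null(roc)) NA_real_ else roc$auc,
                 roc = roc, threshold = threshold, per_image = per),
            class = "masegnet_metrics")
}

#' @export
print.masegnet_metrics <- function(x, ...) {
  cat("Pixel-level segmentation metrics (micro, threshold ",
      x$threshold, ")\n", sep = "")
  cat(sprintf("  accuracy %.4f | dice %.4f | iou %.4f | auc %s\n",
              x$accuracy, x$dice, x$iou,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  cat("  counts: TP", x$counts$TP, "TN", x$counts$TN,
      "FP", x$counts$FP, "FN", x$counts$FN, "\n")
  invisible(x)
}

#' Serialise a metrics report to JSON (and back)
#'
#' @param metrics a `masegnet_metrics` object.
#' @param path destination JSON file.
#' @return `path` (`metrics_to_json`); a `masegnet_metrics` list
#'   (`metrics_from_json`).
#' @export
metrics_to_json <- function(metrics, path) {
  out <- unclass(metrics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname metrics_to_json
#' @export
metrics_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_image <- as.data.frame(x$per_image)
  structure(x, class = "masegnet_metrics")
}
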