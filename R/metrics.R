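# Evaluation metrics from globally accumulated per-class pixel tallies:
# intersection-over-union and Dice on the lesion (foreground) class,
# overall pixel accuracy, and Cohen's kappa with the chance-agreement term
# P_e = sum_c pred_area_c * label_area_c / total^2.

#' Per-class pixel confusion tallies
#'
#' Holds, for each class, the intersection area between prediction and
#' ground truth, the predicted area and the labelled area.  Tallies are
#' accumulated globally over an evaluation split with [accumulate()], so
#' metrics follow the area definitions of the confusion-matrix formulation
#' rather than per-image averages.
#'
#' @param num_classes number of classes (2 for lesion vs background).
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(num_classes = 2L) {
  z <- numeric(num_classes)
  structure(list(intersect_area = z, pred_area = z, label_area = z,
                 num_classes = as.integer(num_classes)),
            class = "confusion_counts")
}

#' Accumulate prediction/truth tallies
#'
#' @param pred,truth integer class-label arrays of identical shape.
#' @param counts a [confusion_counts()] to increment (fresh tallies when
#'   `NULL`).
#' @param num_classes number of classes when `counts` is `NULL`.
#' @return the updated `confusion_counts`.
#' @export
accumulate <- function(pred, truth, counts = NULL, num_classes = 2L) {
  if (is.null(counts)) counts <- confusion_counts(num_classes)
  if (length(pred) != length(truth) ||
      (!is.null(dim(pred)) && !is.null(dim(truth)) &&
       !identical(dim(pred), dim(truth))))
    stop("pred and truth must have identical shape")
  k <- counts$num_classes
  p <- as.integer(pred)
  t <- as.integer(truth)
  if (any(p < 0L | p >= k) || any(t < 0L | t >= k))
    stop("labels must lie in 0..", k - 1L)
  counts$pred_area <- counts$pred_area + tabulate(p + 1L, k)
  counts$label_area <- counts$label_area + tabulate(t + 1L, k)
  counts$intersect_area <- counts$intersect_area +
    tabulate(ifelse(p == t, p + 1L, 0L), k)
  counts
}

# foreground (lesion) tallies
.fg <- function(counts) {
  tp <- counts$intersect_area[2]
  list(tp = tp, fp = counts$pred_area[2] - tp,
       fn = counts$label_area[2] - tp)
}

#' Segmentation metrics from accumulated tallies
#'
#' `iou()` is `TP / (TP + FP + FN)` on the lesion class; `accuracy()` the
#' overall pixel accuracy (summed intersection area over summed predicted
#' area across classes); `kappa()` the chance-corrected agreement
#' `(Acc - P_e) / (1 - P_e)`; `dice_coeff()` the Sorensen-Dice overlap
#' `2|A∩B| / (|A| + |B|)` on the lesion class.  When neither prediction nor
#' truth contains any foreground, `iou()` and `dice_coeff()` are defined as
#' 1 (perfect agreement on absence); when prediction and truth are the same
#' single-class constant, `kappa()` is defined as 1.
#'
#' @param counts a [confusion_counts()].
#' @return a fraction (kappa in [-1, 1], the others in [0, 1]).
#' @export
iou <- function(counts) {
  f <- .fg(counts)
  den <- f$tp + f$fp + f$fn
  if (den == 0) return(1)
  f$tp / den
}

#' @rdname iou
#' @export
accuracy <- function(counts) {
  sum(counts$intersect_area) / sum(counts$pred_area)
}

#' @rdname iou
#' @export
kappa <- function(counts) {
  total <- sum(counts$pred_area)
  acc <- accuracy(counts)
  pe <- sum(counts$pred_area * counts$label_area) / total^2
  if (1 - pe < .Machine$double.eps) return(if (acc == 1) 1 else 0)
  (acc - pe) / (1 - pe)
}

#' @rdname iou
#' @export
dice_coeff <- function(counts) {
  f <- .fg(counts)
  den <- 2 * f$tp + f$fp + f$fn
  if (den == 0) return(1)
  2 * f$tp / den
}

#' Metric report
#'
#' @param counts a [confusion_counts()].
#' @param percent logical; report percentages rather than fractions.
#' @return an object of class `metric_report` with `iou`, `acc`, `kappa`,
#'   `dice`.
#' @export
metric_report <- function(counts, percent = FALSE) {
  s <- if (percent) 100 else 1
  structure(list(iou = s * iou(counts), acc = s * accuracy(counts),
                 kappa = s * kappa(counts), dice = s * dice_coeff(counts),
                 percent = percent),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  u <- if (x$percent) " (%)" else ""
  cat(sprintf("IoU%s\tAcc%s\tKappa%s\tDice%s\n", u, u, u, u))
  cat(sprintf("%.2f\t%.2f\t%.2f\t%.2f\n", x$iou, x$acc, x$kappa, x$dice))
  invisible(x)
}
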