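# Training losses: pixel-wise cross-entropy over class probabilities, soft
# Dice loss on the foreground probability, binary cross-entropy, their
# 0.7/0.3 mixture, and the deep-supervision sum over the fused and side
# outputs.
#
# Probability maps are (H, W, C, N) arrays summing to 1 over the class
# dimension; targets are integer class labels of shape (H, W, N).

.as_prob_map <- function(pred) {
  d <- dim(pred)
  if (is.null(d) || length(d) < 3L)
    stop("pred must be an (H, W, C[, N]) probability array")
  if (length(d) == 3L) dim(pred) <- c(d, 1L)
  pred
}

.as_target <- function(target, d) {
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  if (!all(dim(target) == d[c(1, 2, 4)]))
    stop("target shape does not match prediction")
  if (any(target < 0) || any(target >= d[3]))
    stop("target labels must lie in 0..", d[3] - 1L)
  target
}

.check_normalized <- function(pred, tol = 1e-3) {
  d <- dim(pred)
  cs <- colSums(matrix(aperm(pred, c(3, 1, 2, 4)), d[3]))
  if (max(abs(cs - 1)) > tol)
    stop("pred is not normalized over classes (max deviation ",
         signif(max(abs(cs - 1)), 3), ")")
}

#' Pixel-wise losses for binary segmentation
#'
#' `cross_entropy()` is the mean over pixels of the negative log probability
#' of the true class (log clamped at 1e-12).  `dice_loss()` is the soft
#' Sorensen-Dice loss `1 - (2 * sum(p1 * t) + eps) / (sum(p1) + sum(t) + eps)`
#' on the foreground (class 1) probability.  `bce_loss()` is the mean
#' per-pixel binary cross-entropy on the foreground probability.
#' `mixture_loss()` is the weighted combination `w_ce * CE + w_dice * Dice`
#' with default weights 0.7 and 0.3.
#'
#' @param pred probability array (H, W, C[, N]) with class sums of 1; for
#'   `bce_loss()` alternatively a plain (H, W[, N]) foreground-probability
#'   array.
#' @param target integer class labels (H, W[, N]), values in `0..C-1`.
#' @param eps smoothing constant of the Dice loss.
#' @return a non-negative scalar.
#' @export
cross_entropy <- function(pred, target) {
  pred <- .as_prob_map(pred)
  d <- dim(pred)
  target <- .as_target(target, d)
  .check_normalized(pred)
  lin <- .true_class_index(d, target)
  -mean(log(pmax(pred[lin], 1e-12)))
}

#' @rdname cross_entropy
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  pred <- .as_prob_map(pred)
  d <- dim(pred)
  target <- .as_target(target, d)
  p1 <- pred[, , 2, , drop = FALSE]
  t1 <- as.numeric(target == 1)
  1 - (2 * sum(p1 * t1) + eps) / (sum(p1) + sum(t1) + eps)
}

#' @rdname cross_entropy
#' @export
bce_loss <- function(pred, target) {
  d <- dim(pred)
  p1 <- if (!is.null(d) && length(d) >= 3L && d[3] >= 2L)
    .as_prob_map(pred)[, , 2, , drop = TRUE]
  else pred
  t1 <- as.numeric(target == 1)
  p1 <- pmin(pmax(as.numeric(p1), 1e-12), 1 - 1e-12)
  -mean(t1 * log(p1) + (1 - t1) * log(1 - p1))
}

#' Loss mixture weights
#'
#' @param w_ce,w_dice non-negative weights of the cross-entropy and Dice
#'   components (defaults 0.7 and 0.3).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w_ce = 0.7, w_dice = 0.3) {
  stopifnot(w_ce >= 0, w_dice >= 0)
  structure(list(w_ce = w_ce, w_dice = w_dice), class = "loss_weights")
}

#' @rdname cross_entropy
#' @param w a [loss_weights()].
#' @export
mixture_loss <- function(pred, target, w = loss_weights()) {
  w$w_ce * cross_entropy(pred, target) + w$w_dice * dice_loss(pred, target)
}

#' Deep-supervision loss over fused and side outputs
#'
#' Sums the selected loss over the fused map and all six side outputs,
#' equally weighted; with `fused_only = TRUE` only the fused map enters
#' (reproducing the single-output loss exactly).
#'
#' @param outputs list with elements `fused` and `sides` (as returned by
#'   [seunet_forward()] after a softmax), or a plain list of probability
#'   maps.
#' @param target integer class labels (H, W[, N]).
#' @param w a [loss_weights()] (mixture arm only).
#' @param loss one of `"mixture"`, `"ce"`, `"dice"`, `"bce"` -- the four
#'   configurable training arms.
#' @param fused_only logical; restrict to the fused output.
#' @return a non-negative scalar.
#' @export
supervised_loss <- function(outputs, target, w = loss_weights(),
                            loss = c("mixture", "ce", "dice", "bce"),
                            fused_only = FALSE) {
  loss <- match.arg(loss)
  maps <- if (!is.null(outputs$fused))
    c(list(outputs$fused), if (!fused_only) outputs$sides)
  else if (fused_only) outputs[1] else outputs
  one <- function(p) switch(loss,
    mixture = mixture_loss(p, target, w),
    ce = cross_entropy(p, target),
    dice = dice_loss(p, target),
    bce = bce_loss(p, target))
  sum(vapply(maps, one, numeric(1)))
}

#' Channel softmax of a logit map
#'
#' @param x logits, (H, W, C[, N]) array.
#' @return probability array of the same shape with class sums of 1.
#' @export
softmax_classes <- function(x) {
  x <- .as_feature_map(x)
  ag_softmax_c(ag_const(x))$value
}
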