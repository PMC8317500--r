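# Evaluation statistics for pixel-label segmentation and the Dice +
# cross-entropy training objective.

#' Pixel confusion counts
#'
#' Tallies the (k+1) x (k+1) matrix `p` with `p[i+1, j+1]` = number of
#' pixels whose true label is `i` and predicted label is `j`, for labels
#' `0..k` (0 = background).
#'
#' @param pred,truth integer label grids of identical shape with values in
#'   `0..k`
#' @param k number of non-background classes
#' @return an object of class `"confusion_counts"`: a list with the matrix
#'   `p` and `k`
#' @export
confusion_counts <- function(pred, truth, k = 1L) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shape")
  pv <- as.integer(round(pred))
  tv <- as.integer(round(truth))
  if (any(pv < 0L | pv > k) || any(tv < 0L | tv > k))
    stop(sprintf("labels must lie in 0..%d", k))
  p <- matrix(tabulate(tv * (k + 1L) + pv + 1L, nbins = (k + 1L)^2),
              nrow = k + 1L, byrow = TRUE)
  structure(list(p = p, k = as.integer(k)), class = "confusion_counts")
}

#' Mean intersection-over-union
#'
#' Mean over all k+1 classes (background included) of
#' `TP / (TP + FP + FN)`. A class absent from both prediction and truth
#' (union 0) contributes IoU 1 by the identity-agreement convention; a class
#' absent from exactly one contributes 0.
#'
#' @param c a `"confusion_counts"` object
#' @return mean IoU in \\[0, 1\\]
#' @export
miou <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  p <- c$p
  tp <- diag(p)
  union <- rowSums(p) + colSums(p) - tp
  iou <- ifelse(union == 0, 1, tp / pmax(union, 1e-300))
  mean(iou)
}

#' Precision and recall for one class
#'
#' `TP / (TP + FP)` and `TP / (TP + FN)`; both are 0 by convention when
#' their denominator is 0.
#'
#' @param c a `"confusion_counts"` object
#' @param positive_class class label treated as positive (default 1)
#' @return named numeric vector `c(precision =, recall =)`
#' @export
precision_recall <- function(c, positive_class = 1L) {
  stopifnot(inherits(c, "confusion_counts"))
  i <- positive_class + 1L
  if (i < 1L || i > nrow(c$p)) stop("invalid class index")
  tp <- c$p[i, i]
  fp <- sum(c$p[, i]) - tp
  fn <- sum(c$p[i, ]) - tp
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' F-score
#'
#' `(1 + beta^2) * precision * recall / (beta^2 * precision + recall)`,
#' with value 0 when both inputs are 0. `beta = 1` gives the usual harmonic
#' mean (F1).
#'
#' @param precision,recall values in \\[0, 1\\]
#' @param beta positive recall weight
#' @return the F-score
#' @export
f_score <- function(precision, recall, beta = 1) {
  stopifnot(beta > 0, precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  den <- beta^2 * precision + recall
  if (den == 0) return(0)
  (1 + beta^2) * precision * recall / den
}

#' Dice loss with cross-entropy
#'
#' The compound training objective: one minus the (epsilon-stabilized) Dice
#' coefficient of the soft prediction, plus the pixel-averaged binary
#' cross-entropy with natural logarithms. Probabilities are clamped to
#' `[eps, 1 - eps]` before the logs.
#'
#' When the truth grid is all background, `1 - 2|y n yhat| / (|y| + |yhat|)`
#' degenerates (the soft intersection is identically 0 whatever the
#' prediction), so the Dice term is replaced by the mean predicted
#' foreground: an empty prediction then gives a vanishing loss and excess
#' foreground is still penalized.
#'
#' @param y binary truth grid (values 0/1)
#' @param yhat probability grid of identical shape, values in (0, 1)
#' @param eps clamping and denominator-stabilization constant
#' @return non-negative loss value
#' @export
dice_ce_loss <- function(y, yhat, eps = 1e-7) {
  if (!identical(drop_unit_dims(y), drop_unit_dims(yhat)))
    stop("y and yhat must have identical shape")
  y <- as.numeric(y)
  p <- pmin(pmax(as.numeric(yhat), eps), 1 - eps)
  dice <- if (sum(y) == 0) mean(p) else
    1 - 2 * sum(y * p) / (sum(y) + sum(p) + eps)
  ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  dice + ce
}

# gradient of dice_ce_loss with respect to the pre-sigmoid logit
dice_ce_grad_logit <- function(y, prob, eps = 1e-7) {
  y <- as.numeric(y)
  p <- pmin(pmax(as.numeric(prob), eps), 1 - eps)
  n <- length(p)
  ddice_dp <- if (sum(y) == 0) {
    rep(1 / n, n)
  } else {
    s <- sum(y * p)
    d <- sum(y) + sum(p) + eps
    -2 * y / d + 2 * s / d^2
  }
  ddice_dp * p * (1 - p) + (p - y) / n
}

#' Full metric bundle for one predicted mask
#'
#' @param pred_mask,truth_mask binary label grids
#' @param prob optional probability grid for the Dice+CE loss; when missing
#'   the loss is computed from the hard mask clamped away from 0/1
#' @param beta F-score beta
#' @return a named list with `miou`, `precision`, `recall`, `f_score`,
#'   `dice_ce`
#' @export
metric_bundle <- function(pred_mask, truth_mask, prob = NULL, beta = 1) {
  cc <- confusion_counts(pred_mask, truth_mask, k = 1L)
  pr <- precision_recall(cc, 1L)
  if (is.null(prob)) prob <- pmin(pmax(as.numeric(pred_mask), 1e-7), 1 - 1e-7)
  list(miou = miou(cc),
       precision = unname(pr["precision"]),
       recall = unname(pr["recall"]),
       f_score = f_score(unname(pr["precision"]), unname(pr["recall"]), beta),
       dice_ce = dice_ce_loss(truth_mask,
                              array(prob, dim = dim(as.array(truth_mask)))))
}

#' TP/FP/FN color overlay
#'
#' Renders the comparison of a predicted and a true binary mask as an RGB
#' image: true positives red, false positives blue, false negatives green,
#' true negatives black.
#'
#' @param pred_mask,truth_mask binary grids of identical shape
#' @return an H x W x 3 array in \\[0, 1\\]
#' @export
segmentation_overlay <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop("masks must have identical shape")
  p <- as.numeric(pred_mask) > 0.5
  t <- as.numeric(truth_mask) > 0.5
  out <- array(0, dim = c(dim(as.array(pred_mask))[1:2], 3L))
  out[, , 1][p & t] <- 1      # TP red
  out[, , 3][p & !t] <- 1     # FP blue
  out[, , 2][!p & t] <- 1     # FN green
  out
}
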