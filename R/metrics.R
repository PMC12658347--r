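# Segmentation metrics and the training objective.
#
# Metrics follow the standard confusion-count definitions with mIoU averaged
# over the background and lesion classes (k = 1 foreground class). When a
# class is absent from both prediction and ground truth its IoU (and the
# corresponding rate) is defined as 1; when absent from exactly one, 0.
# HD95 is the 95th percentile of the pooled directed boundary-to-boundary
# Euclidean distances in both directions, with boundary pixels defined as
# mask pixels having at least one background 4-neighbour (pixels outside the
# image count as background).

check_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0 and 1", what), call. = FALSE)
  }
  invisible(m)
}

#' Pixel confusion counts between a predicted and a reference binary mask
#'
#' @param pred_mask,gt_mask binary (0/1) arrays of identical shape.
#' @return list of class `dermseg_confusion` with integer `TP`, `TN`, `FP`,
#'   `FN` and `k = 1`.
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (!identical(dim2(pred_mask), dim2(gt_mask))) {
    stop("prediction and ground truth shapes differ", call. = FALSE)
  }
  check_binary(pred_mask, "prediction")
  check_binary(gt_mask, "ground truth")
  p <- as.logical(pred_mask)
  g <- as.logical(gt_mask)
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g), k = 1L),
            class = "dermseg_confusion")
}

dim2 <- function(x) dim(x) %||% length(x)

add_confusion <- function(a, b) {
  structure(list(TP = a$TP + b$TP, TN = a$TN + b$TN,
                 FP = a$FP + b$FP, FN = a$FN + b$FN, k = 1L),
            class = "dermseg_confusion")
}

safe_ratio <- function(num, den, both_absent) {
  if (den == 0) return(if (both_absent) 1 else 0)
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' mIoU averages the intersection-over-union of the background and lesion
#' classes (each computed with that class treated as positive); DSC is
#' `2TP / (2TP + FP + FN)`; Acc, Sen and Spe are the usual rates. A class
#' absent from both masks contributes the defined value 1.
#'
#' @param c a `dermseg_confusion`.
#' @return list of class `dermseg_metrics` with fields `mIoU`, `DSC`, `Acc`,
#'   `Sen`, `Spe` (fractions in `[0, 1]`) and the `confusion` counts.
#' @export
compute_metrics <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  stopifnot(tot > 0)
  iou_fg <- safe_ratio(c$TP, c$TP + c$FP + c$FN, c$TP + c$FP + c$FN == 0)
  iou_bg <- safe_ratio(c$TN, c$TN + c$FN + c$FP, c$TN + c$FN + c$FP == 0)
  structure(list(
    mIoU = (iou_fg + iou_bg) / 2,
    DSC = safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN,
                     c$TP + c$FP + c$FN == 0),
    Acc = (c$TP + c$TN) / tot,
    Sen = safe_ratio(c$TP, c$TP + c$FN, c$TP + c$FN + c$FP == 0),
    Spe = safe_ratio(c$TN, c$TN + c$FP, c$TN + c$FP + c$FN == 0),
    confusion = c), class = "dermseg_metrics")
}

#' @export
print.dermseg_metrics <- function(x, ...) {
  cat(sprintf("mIoU %.2f%%  DSC %.2f%%  Acc %.2f%%  Sen %.2f%%  Spe %.2f%%",
              100 * x$mIoU, 100 * x$DSC, 100 * x$Acc, 100 * x$Sen,
              100 * x$Spe))
  if (!is.null(x$HD95)) cat(sprintf("  HD95 %.2f", x$HD95))
  cat("\n")
  invisible(x)
}

# boundary pixels: mask pixels with at least one background 4-neighbour
# (outside the image counts as background); returned as an n x 2 matrix of
# (row, col) coordinates.
boundary_pixels <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

#' 95th-percentile symmetric boundary distance (HD95)
#'
#' @param pred_mask,gt_mask binary masks of identical shape.
#' @param spacing pixel spacing `(row, col)`.
#' @return length in pixels. Both masks empty gives 0; exactly one empty
#'   returns the image diagonal as a sentinel.
#' @export
hd95 <- function(pred_mask, gt_mask, spacing = c(1, 1)) {
  if (!identical(dim2(pred_mask), dim2(gt_mask))) {
    stop("prediction and ground truth shapes differ", call. = FALSE)
  }
  pe <- sum(pred_mask) == 0
  ge <- sum(gt_mask) == 0
  if (pe && ge) return(0)
  if (pe || ge) {
    return(sqrt(sum((dim2(pred_mask) * spacing)^2)))
  }
  a <- boundary_pixels(pred_mask)
  b <- boundary_pixels(gt_mask)
  a <- sweep(a, 2L, spacing, `*`)
  b <- sweep(b, 2L, spacing, `*`)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  directed <- c(sqrt(apply(d2, 1L, min)), sqrt(apply(d2, 2L, min)))
  unname(stats::quantile(directed, 0.95, type = 7))
}

#' Combined cross-entropy + soft Dice loss on logits
#'
#' `w_ce * BCE(sigma(logit), gt) + w_dice * (1 - (2*sum(p*g) + eps) /
#' (sum(p) + sum(g) + eps))` with `p = sigma(logit)` and smoothing
#' `eps = 1`. BCE is averaged over pixels; the Dice term is computed over all
#' pixels jointly.
#'
#' @param logits numeric array of raw scores.
#' @param gt_mask binary array of the same total size.
#' @param weights numeric pair `(w_ce, w_dice)`.
#' @param eps Dice smoothing term.
#' @return scalar loss.
#' @export
combined_loss <- function(logits, gt_mask, weights = c(1, 1), eps = 1) {
  check_binary(gt_mask, "ground truth")
  stopifnot(length(logits) == length(gt_mask))
  p <- sigmoid(as.numeric(logits))
  g <- as.numeric(gt_mask)
  # numerically stable BCE-with-logits
  z <- as.numeric(logits)
  bce <- mean(pmax(z, 0) - z * g + log1p(exp(-abs(z))))
  dice <- 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  weights[1] * bce + weights[2] * dice
}

# gradient of combined_loss w.r.t. the logits (used by the trainer)
combined_loss_grad <- function(logits, gt_mask, weights = c(1, 1), eps = 1) {
  z <- as.numeric(logits)
  p <- sigmoid(z)
  g <- as.numeric(gt_mask)
  n <- length(z)
  dbce <- (p - g) / n
  sp <- sum(p); sg <- sum(g); spg <- sum(p * g)
  den <- sp + sg + eps
  ddice_dp <- -(2 * g * den - (2 * spg + eps)) / den^2
  dp <- p * (1 - p)
  grad <- weights[1] * dbce + weights[2] * ddice_dp * dp
  array(grad, dim2(logits))
}
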