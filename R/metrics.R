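#' Overlap metrics for binary segmentation masks
#'
#' `dice_coefficient()` computes `2|A∩B| / (|A| + |B|)` and `iou()` computes
#' `|A∩B| / |A∪B|` between a predicted and a reference binary mask.  When
#' both masks are empty the overlap is perfect by convention and both
#' metrics return 1.
#'
#' @param pred,truth binary arrays of identical shape (values 0/1; logical
#'   accepted).
#' @return a scalar in `[0, 1]`.
#' @examples
#' a <- matrix(0, 8, 8); a[2:4, 2:4] <- 1
#' b <- matrix(0, 8, 8); b[3:5, 2:4] <- 1
#' dice_coefficient(a, b)
#' iou(a, b)
#' @export
dice_coefficient <- function(pred, truth) {
  check_mask_pair(pred, truth)
  inter <- sum(pred * truth)
  tot <- sum(pred) + sum(truth)
  if (tot == 0) return(1)
  2 * inter / tot
}

#' @rdname dice_coefficient
#' @export
iou <- function(pred, truth) {
  check_mask_pair(pred, truth)
  inter <- sum(pred * truth)
  uni <- sum(pred) + sum(truth) - inter
  if (uni == 0) return(1)
  inter / uni
}

check_mask_pair <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    abort_sonoseg("pred and truth have different shapes",
                  class = "sonoseg_shape_error")
  }
  invisible(TRUE)
}

#' Smoothed soft Dice loss
#'
#' `1 - (2*sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)`; differentiable
#' in the prediction, and equal to 0 for a perfect prediction (the smooth
#' term rescues the both-empty 0/0 case).
#'
#' @param pred probability grid in `[0, 1]`.
#' @param truth binary grid, same shape.
#' @param smooth smoothing constant (default 1).
#' @return scalar loss `>= 0`.
#' @export
soft_dice_loss <- function(pred, truth, smooth = 1) {
  check_mask_pair(pred, truth)
  1 - (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)
}

#' Smoothed Jaccard distance
#'
#' The auxiliary training loss: with intersection `I = sum(p*t)` and total
#' `U = sum(p) + sum(t)`, returns `(1 - (I + smooth) / (U - I + smooth)) *
#' smooth` (the conventional smooth-factor-scaled form; set `scaled = FALSE`
#' for the unscaled distance in `[0, 1]`).
#'
#' @inheritParams soft_dice_loss
#' @param smooth smoothing constant, default 100.
#' @param scaled multiply by `smooth` (default) or not.
#' @return scalar loss; 0 when both masks are empty.
#' @export
jaccard_distance <- function(pred, truth, smooth = 100, scaled = TRUE) {
  check_mask_pair(pred, truth)
  I <- sum(pred * truth)
  U <- sum(pred) + sum(truth)
  val <- 1 - (I + smooth) / (U - I + smooth)
  if (scaled) val * smooth else val
}

#' Pixelwise binary accuracy
#'
#' Fraction of pixels whose thresholded prediction equals the truth.  A
#' probability exactly at the threshold counts as positive.  With heavy
#' class imbalance this metric saturates near 1 even for poor masks, which
#' is why Dice/IoU are the primary quality measures.
#'
#' @inheritParams soft_dice_loss
#' @param threshold probability cut, default 0.5.
#' @return scalar in `[0, 1]`.
#' @export
binary_accuracy <- function(pred, truth, threshold = 0.5) {
  check_mask_pair(pred, truth)
  mean((pred >= threshold) == (truth > 0))
}
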