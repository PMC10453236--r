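# Dice loss and the six evaluation statistics (midce, accuracy, recall,
# miou, fwavacc, F1), computed per image from the 2x2 confusion matrix and
# averaged over the evaluation set.

#' Soft dice loss
#'
#' `1 - (2 * sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)`, computed per
#' sample (first array axis when `probabilities` has a batch axis) and
#' averaged over the batch.
#'
#' @param probabilities predicted foreground probabilities in `[0, 1]`;
#'   array shaped like `target_mask` or with a leading batch axis.
#' @param target_mask binary ground-truth mask.
#' @param smooth additive smoothing term.
#' @param batched treat the first axis as the batch axis; by default
#'   inferred (TRUE when the arrays have 4 axes).
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probabilities, target_mask, smooth = 1e-6,
                      batched = NULL) {
  if (!identical(dim2(probabilities), dim2(target_mask))) {
    stop("dice_loss: shape mismatch", call. = FALSE)
  }
  if (is.null(batched)) batched <- length(dim2(probabilities)) >= 4L
  if (!batched) {
    dim(probabilities) <- c(1L, dim2(probabilities))
    dim(target_mask) <- c(1L, dim2(target_mask))
  }
  B <- dim(probabilities)[1]
  pm <- mat2pb(probabilities, B)          # (B, pixels) rows are samples
  tm <- mat2pb(target_mask, B)
  per <- 1 - (2 * rowSums(pm * tm) + smooth) /
    (rowSums(pm) + rowSums(tm) + smooth)
  mean(per)
}

# reshape a batch-first array to a (B, rest) matrix; batch index is the
# fastest-varying axis in R's column-major layout, so rows are samples
mat2pb <- function(x, B) {
  dim(x) <- c(B, length(x) %/% B)
  x
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# gradient of dice_loss w.r.t. probabilities (same batching rules)
dice_loss_grad <- function(probabilities, target_mask, smooth = 1e-6,
                           batched = NULL) {
  if (is.null(batched)) batched <- length(dim2(probabilities)) >= 4L
  d0 <- dim2(probabilities)
  if (!batched) dim(probabilities) <- c(1L, d0)
  d <- dim(probabilities)
  B <- d[1]
  pm <- mat2pb(probabilities, B)
  tm <- mat2pb(target_mask, B)
  num <- 2 * rowSums(pm * tm) + smooth
  den <- rowSums(pm) + rowSums(tm) + smooth
  g <- -(2 * tm * den - num) / den^2 / B
  dim(g) <- d0
  g
}

#' Segmentation metrics from a binary prediction / ground-truth pair
#'
#' All six statistics derive from the 2x2 pixel confusion matrix:
#' accuracy `(TP+TN)/N`; foreground recall `TP/(TP+FN)`; dice
#' `2TP/(2TP+FP+FN)` (reported both as `midce` and `f1`); per-class IoU
#' `TP/(TP+FP+FN)` and `TN/(TN+FP+FN)` averaged into `miou`; and
#' frequency-weighted IoU `fwavacc = sum_k freq_k * IoU_k` with class
#' frequencies taken from the ground truth. A class absent from both
#' prediction and truth contributes `zero_division` (default 1) to its
#' ratio.
#'
#' @param pred_mask,gt_mask binary arrays of identical shape.
#' @param zero_division value used when a ratio's denominator is zero.
#' @return a `gctu_metrics` list with fields `midce`, `accuracy`, `recall`,
#'   `miou`, `fwavacc`, `f1`, all in `[0, 1]`.
#' @export
compute_metrics <- function(pred_mask, gt_mask, zero_division = 1) {
  if (!identical(dim2(pred_mask), dim2(gt_mask))) {
    stop("compute_metrics: shape mismatch", call. = FALSE)
  }
  p <- as.vector(pred_mask)
  g <- as.vector(gt_mask)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1))) {
    stop("compute_metrics: masks must be binary (0/1)", call. = FALSE)
  }
  TP <- sum(p == 1 & g == 1)
  TN <- sum(p == 0 & g == 0)
  FP <- sum(p == 1 & g == 0)
  FN <- sum(p == 0 & g == 1)
  N <- TP + TN + FP + FN
  sdiv <- function(num, den) if (den == 0) zero_division else num / den
  dice <- sdiv(2 * TP, 2 * TP + FP + FN)
  iou_fg <- sdiv(TP, TP + FP + FN)
  iou_bg <- sdiv(TN, TN + FP + FN)
  freq_fg <- (TP + FN) / N
  freq_bg <- (TN + FP) / N
  out <- list(midce = dice,
              accuracy = (TP + TN) / N,
              recall = sdiv(TP, TP + FN),
              miou = (iou_fg + iou_bg) / 2,
              fwavacc = freq_fg * iou_fg + freq_bg * iou_bg,
              f1 = dice)
  class(out) <- "gctu_metrics"
  out
}

#' @export
print.gctu_metrics <- function(x, ...) {
  cat(sprintf(
    "midce %.4f  accuracy %.4f  recall %.4f  miou %.4f  fwavacc %.4f  f1 %.4f\n",
    x$midce, x$accuracy, x$recall, x$miou, x$fwavacc, x$f1))
  invisible(x)
}

#' Evaluate a model over a sample set
#'
#' Metrics are computed per image and averaged; `midce` is therefore the
#' mean dice over the set.
#'
#' @param model a [gc_transunet()] model.
#' @param samples list of samples (each with `$image`, `$mask`) as produced
#'   by [generate_dataset()] or [load_dataset()].
#' @param threshold probability threshold for mask binarisation.
#' @param batch_size forward-pass batch size.
#' @return a `gctu_metrics` list of set-averaged statistics.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5, batch_size = 4L) {
  stopifnot(length(samples) >= 1L)
  acc <- NULL
  n <- length(samples)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (ii in idx) {
    x <- stack_images(samples[ii])
    prob <- sigmoid_fwd(model_fwd(model, x, train = FALSE)$y)$y
    for (j in seq_along(ii)) {
      pm <- (prob[j, , , 1] >= threshold) * 1
      mt <- compute_metrics(pm, samples[[ii[j]]]$mask)
      v <- unlist(mt[c("midce", "accuracy", "recall", "miou", "fwavacc", "f1")])
      acc <- if (is.null(acc)) v else acc + v
    }
  }
  out <- as.list(acc / n)
  class(out) <- "gctu_metrics"
  out
}
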