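# Independent oracles used across the suite. Each one is deliberately
# written as plain nested loops (no vectorised shortcuts shared with the
# implementation) so it constitutes a second, independent route to the
# same quantity.

# brute-force scaled dot-product attention: explicit loops over queries,
# keys and channels with explicit exp-normalisation
oracle_attention <- function(q, k, v, bias = NULL) {
  nq <- nrow(q); nk <- nrow(k); d <- ncol(q)
  out <- matrix(0, nq, ncol(v))
  for (i in seq_len(nq)) {
    logits <- numeric(nk)
    for (j in seq_len(nk)) {
      s <- 0
      for (c in seq_len(d)) s <- s + q[i, c] * k[j, c]
      logits[j] <- s / sqrt(d) + if (is.null(bias)) 0 else bias[i, j]
    }
    e <- exp(logits - max(logits))
    p <- e / sum(e)
    for (c in seq_len(ncol(v))) {
      acc <- 0
      for (j in seq_len(nk)) acc <- acc + p[j] * v[j, c]
      out[i, c] <- acc
    }
  }
  out
}

# step-by-step Fused-MBConv composition with explicit spatial loops:
# dwconv3x3 (pad 1) -> gelu -> SE -> 1x1 conv -> + x, for a single sample
oracle_fused_mbconv <- function(x, m) {
  d <- dim(x)                  # (1, H, W, C)
  H <- d[2]; W <- d[3]; C <- d[4]
  dw <- array(0, d)
  for (h in seq_len(H)) for (w in seq_len(W)) for (c in seq_len(C)) {
    acc <- m$dw$w$b[c]
    for (ki in 1:3) for (kj in 1:3) {
      hh <- h + ki - 2L; ww <- w + kj - 2L
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
        acc <- acc + x[1, hh, ww, c] * m$dw$w$W[ki, kj, c]
      }
    }
    dw[1, h, w, c] <- acc
  }
  act <- dw * pnorm(dw)        # exact GELU
  pooled <- numeric(C)
  for (c in seq_len(C)) pooled[c] <- mean(act[1, , , c])
  h1 <- as.vector(pooled %*% m$se$fc1$w$W) + m$se$fc1$w$b
  h1 <- pmax(h1, 0)
  gate <- 1 / (1 + exp(-(as.vector(h1 %*% m$se$fc2$w$W) + m$se$fc2$w$b)))
  gated <- act
  for (c in seq_len(C)) gated[1, , , c] <- act[1, , , c] * gate[c]
  out <- array(0, d)
  for (h in seq_len(H)) for (w in seq_len(W)) for (co in seq_len(C)) {
    acc <- m$proj$w$b[co]
    for (ci in seq_len(C)) {
      acc <- acc + gated[1, h, w, ci] * m$proj$w$W[ci, co]
    }
    out[1, h, w, co] <- acc + x[1, h, w, co]
  }
  out
}

# exhaustive pixel-loop segmentation statistics from two binary masks
oracle_metrics <- function(pred, gt, zero_division = 1) {
  TP <- 0; TN <- 0; FP <- 0; FN <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) TP <- TP + 1
    if (pred[i] == 0 && gt[i] == 0) TN <- TN + 1
    if (pred[i] == 1 && gt[i] == 0) FP <- FP + 1
    if (pred[i] == 0 && gt[i] == 1) FN <- FN + 1
  }
  N <- length(pred)
  z <- function(a, b) if (b == 0) zero_division else a / b
  dice <- z(2 * TP, 2 * TP + FP + FN)
  iou_f <- z(TP, TP + FP + FN)
  iou_b <- z(TN, TN + FP + FN)
  list(midce = dice,
       accuracy = (TP + TN) / N,
       recall = z(TP, TP + FN),
       miou = (iou_f + iou_b) / 2,
       fwavacc = (TP + FN) / N * iou_f + (TN + FP) / N * iou_b,
       f1 = dice)
}

# set every trainable array reachable under the named sub-paths to zero
zero_params <- function(module, patterns) {
  flat <- gctransunet:::nn_collect(module)
  for (nm in names(flat)) {
    if (any(vapply(patterns, function(p) grepl(p, nm), logical(1)))) {
      flat[[nm]][] <- 0
    }
  }
  gctransunet:::nn_restore(module, flat)
}

rand_map <- function(B, H, W, C, seed = 1) {
  set.seed(seed)
  array(rnorm(B * H * W * C), c(B, H, W, C))
}
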