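# Global Token Generator: distill a stage's feature map into w^2 global
# tokens through a Fused-MBConv + 2x2 max-pool pyramid. The tokens are the
# shared queries of that stage's global attention blocks and are computed
# once per stage.

#' Number of pooling steps needed to reduce a feature side to one window
#'
#' @param feature_side stage feature side length (patch units).
#' @param w window side length; `feature_side / w` must be a power of two.
#' @return integer `log2(feature_side / w)`.
#' @export
num_pool_steps <- function(feature_side, w) {
  if (feature_side %% w != 0L) {
    stop(sprintf("feature side %d not divisible by window %d",
                 feature_side, w), call. = FALSE)
  }
  r <- feature_side %/% w
  if (bitwAnd(r, r - 1L) != 0L) {
    stop(sprintf("feature side / window = %d is not a power of two", r),
         call. = FALSE)
  }
  as.integer(round(log2(r)))
}

#' Global token generator module
#'
#' @param C channel count of the stage.
#' @param feature_side stage feature side.
#' @param w window side.
#' @param use_features include the Fused-MBConv feature-extraction stages
#'   (when `FALSE`, only max pooling and the reshape remain).
#' @param se_reduction SE reduction inside the Fused-MBConv blocks.
#' @return a GTG module usable with [generate_global_tokens()].
#' @export
gtg_module <- function(C, feature_side, w, use_features = TRUE,
                       se_reduction = 4L) {
  steps <- num_pool_steps(feature_side, w)
  m <- list(type = "gtg", steps = steps, w = as.integer(w),
            use_features = isTRUE(use_features))
  if (m$use_features && steps > 0L) {
    m$blocks <- lapply(seq_len(steps),
                       function(i) fused_mbconv_module(C, se_reduction))
    names(m$blocks) <- paste0("b", seq_len(steps))
  }
  m
}

gtg_fwd <- function(m, x) {
  caches <- vector("list", m$steps)
  for (i in seq_len(m$steps)) {
    cf <- NULL
    if (m$use_features) {
      f <- fused_fwd(m$blocks[[i]], x)
      x <- f$y
      cf <- f$cache
    }
    p <- maxpool2_fwd(x)
    x <- p$y
    caches[[i]] <- list(fused = cf, pool = p$cache)
  }
  d <- dim(x)
  B <- d[1]; w <- m$w; C <- d[4]
  tok <- aperm(x, c(1L, 3L, 2L, 4L))   # row-major tokens: column fastest
  dim(tok) <- c(B, w * w, C)
  list(y = tok, cache = list(steps = caches, B = B, C = C))
}

gtg_bwd <- function(m, cache, dy) {
  B <- cache$B; w <- m$w; C <- cache$C
  dim(dy) <- c(B, w, w, C)
  dx <- aperm(dy, c(1L, 3L, 2L, 4L))
  gw <- list()
  for (i in rev(seq_len(m$steps))) {
    dx <- maxpool2_bwd(cache$steps[[i]]$pool, dx)
    if (m$use_features) {
      rf <- fused_bwd(m$blocks[[i]], cache$steps[[i]]$fused, dx)
      dx <- rf$dx
      gw <- c(prefix_gw(rf$gw, paste0("blocks/b", i)), gw)
    }
  }
  list(dx = dx, gw = gw)
}

#' Generate global tokens from a stage feature map
#'
#' Applies `log2(side / w)` repetitions of Fused-MBConv + 2x2 stride-2 max
#' pooling, then flattens the resulting w x w map to a row-major token
#' sequence. The channel count is unchanged and the output always carries
#' exactly `w^2` tokens. With `use_features = FALSE` the Fused-MBConv
#' stages are skipped (pooling + reshape only).
#'
#' @param x feature map (B, side, side, C).
#' @param w window side.
#' @param m optional prebuilt [gtg_module()].
#' @param use_features include Fused-MBConv feature extraction (used when
#'   `m` is omitted).
#' @return token array (B, w^2, C).
#' @export
generate_global_tokens <- function(x, w, m = NULL, use_features = TRUE) {
  if (is.null(m)) {
    m <- gtg_module(dim(x)[4], dim(x)[2], w, use_features = use_features)
  }
  gtg_fwd(m, x)$y
}
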