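# Convolutional building blocks of the encoder: squeeze-excitation channel
# gating, the Fused-MBConv residual block, the stage downsampler, and the
# stride-`patch_size` stem.
#
# Module convention: a module is a named list; trainable arrays live under
# `$w`; sub-modules under other names. `*_fwd(m, x)` returns list(y, cache);
# `*_bwd(m, cache, dy)` returns list(dx, gw) where `gw` is a flat named list
# of gradients keyed like `nn_collect(m)` paths.

prefix_gw <- function(gw, name) {
  if (length(gw)) names(gw) <- paste(name, names(gw), sep = "/")
  gw
}

# ---------------------------------------------------------------------------
# module constructors (weights drawn from the current RNG stream)

make_linear <- function(cin, cout, bias = TRUE, sd = 0.02) {
  w <- list(W = init_trunc_normal(c(cin, cout), sd))
  if (bias) w$b <- numeric(cout)
  list(type = "linear", w = w)
}

make_conv2d <- function(k, cin, cout, stride = 1L, pad = 0L, bias = TRUE,
                        sd = 0.02) {
  w <- list(W = init_trunc_normal(c(k, k, cin, cout), sd))
  if (bias) w$b <- numeric(cout)
  list(type = "conv2d", w = w, stride = as.integer(stride),
       pad = as.integer(pad))
}

make_dwconv3 <- function(C, sd = 0.02) {
  list(type = "dwconv3", w = list(W = init_trunc_normal(c(3L, 3L, C), sd),
                                  b = numeric(C)))
}

make_layernorm <- function(C, eps = 1e-5) {
  list(type = "layernorm", w = list(gamma = rep(1, C), beta = numeric(C)),
       eps = eps)
}

make_groupnorm <- function(C, groups = 1L, eps = 1e-6) {
  list(type = "groupnorm", w = list(gamma = rep(1, C), beta = numeric(C)),
       groups = as.integer(groups), eps = eps)
}

make_batchnorm <- function(C, eps = 1e-5) {
  stats <- new.env(parent = emptyenv())
  stats$mean <- numeric(C)
  stats$var <- rep(1, C)
  list(type = "batchnorm", w = list(gamma = rep(1, C), beta = numeric(C)),
       stats = stats, eps = eps)
}

# thin wrappers so composites read uniformly -------------------------------

linear_mod_fwd <- function(m, x) linear_fwd(x, m$w$W, m$w$b)
linear_mod_bwd <- function(m, cache, dy) {
  r <- linear_bwd(cache, dy)
  gw <- list(W = r$W)
  if (!is.null(r$b)) gw$b <- r$b
  list(dx = r$dx, gw = gw)
}

conv2d_mod_fwd <- function(m, x, keep = FALSE) {
  conv2d_fwd(x, m$w$W, m$w$b, stride = m$stride, pad = m$pad, keep = keep)
}
conv2d_mod_bwd <- function(m, cache, dy) {
  r <- conv2d_bwd(cache, dy)
  gw <- list(W = r$W)
  if (!is.null(r$b)) gw$b <- r$b
  list(dx = r$dx, gw = gw)
}

layernorm_mod_fwd <- function(m, x) {
  layernorm_fwd(x, m$w$gamma, m$w$beta, eps = m$eps)
}
layernorm_mod_bwd <- function(m, cache, dy) {
  r <- layernorm_bwd(cache, dy)
  list(dx = r$dx, gw = list(gamma = r$gamma, beta = r$beta))
}

groupnorm_mod_fwd <- function(m, x) {
  groupnorm_fwd(x, m$w$gamma, m$w$beta, groups = m$groups, eps = m$eps)
}
groupnorm_mod_bwd <- function(m, cache, dy) {
  r <- groupnorm_bwd(cache, dy)
  list(dx = r$dx, gw = list(gamma = r$gamma, beta = r$beta))
}

batchnorm_mod_fwd <- function(m, x, train = FALSE) {
  batchnorm_fwd(x, m$w$gamma, m$w$beta, m$stats, train = train, eps = m$eps)
}
batchnorm_mod_bwd <- function(m, cache, dy) {
  r <- batchnorm_bwd(cache, dy)
  list(dx = r$dx, gw = list(gamma = r$gamma, beta = r$beta))
}

# ---------------------------------------------------------------------------
# squeeze-and-excitation

#' Squeeze-excitation module
#'
#' Channel gating from globally pooled statistics: the feature map is
#' average-pooled over space, passed through a two-layer bottleneck
#' (`C -> C/reduction -> C`, ReLU then sigmoid), and the resulting per-channel
#' gate in (0, 1) rescales the input. Output shape equals input shape.
#'
#' @param C channel count.
#' @param reduction bottleneck reduction ratio (reduced width is floored
#'   at 1).
#' @return an SE module usable with [squeeze_excitation()].
#' @export
se_module <- function(C, reduction = 4L) {
  if (reduction <= 0) stop("se reduction must be positive", call. = FALSE)
  r <- max(1L, C %/% as.integer(reduction))
  list(type = "se",
       fc1 = make_linear(C, r),
       fc2 = make_linear(r, C))
}

se_fwd <- function(m, x) {
  d <- dim(x)
  B <- d[1]; HW <- d[2] * d[3]; C <- d[4]
  xm <- x
  dim(xm) <- c(B * HW, C)
  bgrp <- rep_len(seq_len(B), B * HW)     # batch index cycles fastest
  pooled <- rowsum(xm, group = bgrp) / HW # (B, C)
  f1 <- linear_mod_fwd(m$fc1, pooled)
  r1 <- relu_fwd(f1$y)
  f2 <- linear_mod_fwd(m$fc2, r1$y)
  sg <- sigmoid_fwd(f2$y)                 # gate (B, C)
  gate_x <- sg$y[bgrp, , drop = FALSE]
  y <- xm * gate_x
  dim(y) <- d
  list(y = y, cache = list(xm = xm, bgrp = bgrp, HW = HW, d = d,
                           f1 = f1$cache, r1 = r1$cache, f2 = f2$cache,
                           sg = sg$cache, gate_x = gate_x))
}

se_bwd <- function(m, cache, dy) {
  d <- cache$d
  C <- d[4]
  dym <- mat2(dy, C)
  dgate <- rowsum(dym * cache$xm, group = cache$bgrp)
  dx1 <- dym * cache$gate_x
  r2 <- linear_mod_bwd(m$fc2, cache$f2, sigmoid_bwd(cache$sg, dgate))
  r1 <- linear_mod_bwd(m$fc1, cache$f1, relu_bwd(cache$r1, r2$dx))
  dpool <- r1$dx / cache$HW
  dx <- dx1 + dpool[cache$bgrp, , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, gw = c(prefix_gw(r1$gw, "fc1"), prefix_gw(r2$gw, "fc2")))
}

#' Apply squeeze-excitation channel gating
#'
#' @param x feature map array (B, H, W, C).
#' @param m SE module from [se_module()]; a fresh one is created when
#'   omitted.
#' @param reduction bottleneck reduction ratio used when `m` is omitted.
#' @return gated feature map with the same shape as `x`.
#' @export
squeeze_excitation <- function(x, m = NULL, reduction = 4L) {
  if (is.null(m)) m <- se_module(dim(x)[4], reduction)
  se_fwd(m, x)$y
}

# ---------------------------------------------------------------------------
# Fused-MBConv: dwconv3x3 -> GELU -> SE -> conv1x1, plus identity shortcut

#' Fused-MBConv residual block module
#'
#' The block computes `x + Conv1x1(SE(GELU(DWConv3x3(x))))`; spatial size
#' and channel count are preserved, and the block is exactly the identity
#' when the final 1x1 projection is zero.
#'
#' @param C channel count.
#' @param se_reduction SE bottleneck reduction ratio.
#' @return a Fused-MBConv module usable with [fused_mbconv()].
#' @export
fused_mbconv_module <- function(C, se_reduction = 4L) {
  list(type = "fused_mbconv",
       dw = make_dwconv3(C),
       se = se_module(C, se_reduction),
       proj = make_linear(C, C))          # 1x1 conv == channel-wise linear
}

fused_fwd <- function(m, x) {
  f1 <- dwconv3_fwd(x, m$dw$w$W, m$dw$w$b)
  g1 <- gelu_fwd(f1$y)
  s1 <- se_fwd(m$se, g1$y)
  p1 <- linear_mod_fwd(m$proj, s1$y)
  list(y = p1$y + x,
       cache = list(f1 = f1$cache, g1 = g1$cache, s1 = s1$cache,
                    p1 = p1$cache))
}

fused_bwd <- function(m, cache, dy) {
  rp <- linear_mod_bwd(m$proj, cache$p1, dy)
  rs <- se_bwd(m$se, cache$s1, rp$dx)
  dg <- gelu_bwd(cache$g1, rs$dx)
  rd <- dwconv3_bwd(cache$f1, dg)
  list(dx = rd$dx + dy,
       gw = c(prefix_gw(list(W = rd$W, b = rd$b), "dw"),
              prefix_gw(rs$gw, "se"),
              prefix_gw(rp$gw, "proj")))
}

#' Apply a Fused-MBConv block
#'
#' @param x feature map array (B, H, W, C).
#' @param m module from [fused_mbconv_module()]; a fresh one is created when
#'   omitted.
#' @param se_reduction SE reduction used when `m` is omitted.
#' @return feature map with the same shape as `x`.
#' @export
fused_mbconv <- function(x, m = NULL, se_reduction = 4L) {
  if (is.null(m)) m <- fused_mbconv_module(dim(x)[4], se_reduction)
  fused_fwd(m, x)$y
}

# ---------------------------------------------------------------------------
# downsample: [Fused-MBConv] -> LayerNorm -> 3x3 stride-2 conv (C -> 2C)

#' Stage downsampler module
#'
#' Halves each spatial axis and doubles the channel count: an optional
#' Fused-MBConv refinement, channel layer normalisation, then a 3x3
#' stride-2 pad-1 convolution mapping C to 2C. The Fused-MBConv stage is
#' dropped when `use_fused = FALSE` (ablation switch).
#'
#' @param C input channel count.
#' @param use_fused include the Fused-MBConv refinement.
#' @param se_reduction SE reduction inside the Fused-MBConv.
#' @return a downsample module usable with [downsample()].
#' @export
downsample_module <- function(C, use_fused = TRUE, se_reduction = 4L) {
  m <- list(type = "downsample", use_fused = isTRUE(use_fused),
            norm = make_layernorm(C),
            conv = make_conv2d(3L, C, 2L * C, stride = 2L, pad = 1L))
  if (m$use_fused) m$fused <- fused_mbconv_module(C, se_reduction)
  m
}

downsample_fwd <- function(m, x, keep = FALSE) {
  d <- dim(x)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stop(sprintf("downsample requires even spatial size, got %dx%d",
                 d[2], d[3]), call. = FALSE)
  }
  cf <- NULL
  if (m$use_fused) {
    f <- fused_fwd(m$fused, x)
    x <- f$y
    cf <- f$cache
  }
  n <- layernorm_mod_fwd(m$norm, x)
  cv <- conv2d_mod_fwd(m$conv, n$y, keep = keep)
  list(y = cv$y, cache = list(fused = cf, norm = n$cache, conv = cv$cache))
}

downsample_bwd <- function(m, cache, dy) {
  rc <- conv2d_mod_bwd(m$conv, cache$conv, dy)
  rn <- layernorm_mod_bwd(m$norm, cache$norm, rc$dx)
  gw <- c(prefix_gw(rn$gw, "norm"), prefix_gw(rc$gw, "conv"))
  dx <- rn$dx
  if (m$use_fused) {
    rf <- fused_bwd(m$fused, cache$fused, dx)
    dx <- rf$dx
    gw <- c(prefix_gw(rf$gw, "fused"), gw)
  }
  list(dx = dx, gw = gw)
}

#' Downsample a feature map (halve spatial size, double channels)
#'
#' @param x feature map array (B, H, W, C) with even H and W.
#' @param m module from [downsample_module()]; created fresh when omitted.
#' @param use_fused include the Fused-MBConv refinement (used when `m` is
#'   omitted).
#' @return feature map of shape (B, H/2, W/2, 2C).
#' @export
downsample <- function(x, m = NULL, use_fused = TRUE) {
  if (is.null(m)) m <- downsample_module(dim(x)[4], use_fused = use_fused)
  downsample_fwd(m, x)$y
}

# ---------------------------------------------------------------------------
# stem: stride-patch_size convolutional embedding + one Fused-MBConv

#' Patch-embedding stem module
#'
#' A `patch_size`-stride convolution (kernel size = stride, i.e.
#' non-overlapping patches) embedding the 3-channel image into `base_dim`
#' channels, refined by one Fused-MBConv block.
#'
#' @param patch_size stem stride in pixels.
#' @param base_dim embedding width.
#' @param se_reduction SE reduction inside the Fused-MBConv.
#' @return a stem module usable with [stem()].
#' @export
stem_module <- function(patch_size, base_dim, se_reduction = 4L) {
  list(type = "stem",
       embed = make_conv2d(patch_size, 3L, base_dim, stride = patch_size,
                           pad = 0L),
       fused = fused_mbconv_module(base_dim, se_reduction))
}

stem_fwd <- function(m, x, keep = FALSE) {
  d <- dim(x)
  p <- m$embed$stride
  if (d[2] %% p != 0L || d[3] %% p != 0L) {
    stop(sprintf("stem: input %dx%d not divisible by patch size %d",
                 d[2], d[3], p), call. = FALSE)
  }
  cv <- conv2d_mod_fwd(m$embed, x, keep = keep)
  f <- fused_fwd(m$fused, cv$y)
  list(y = f$y, cache = list(embed = cv$cache, fused = f$cache))
}

stem_bwd <- function(m, cache, dy) {
  rf <- fused_bwd(m$fused, cache$fused, dy)
  re <- conv2d_mod_bwd(m$embed, cache$embed, rf$dx)
  list(dx = re$dx,
       gw = c(prefix_gw(re$gw, "embed"), prefix_gw(rf$gw, "fused")))
}

#' Embed an image into patch tokens (stem)
#'
#' @param image array (B, H, W, 3) with H, W divisible by the patch size.
#' @param cfg a [gctu_config()].
#' @param m optional prebuilt [stem_module()].
#' @return feature map (B, H/patch, W/patch, base_dim).
#' @export
stem <- function(image, cfg, m = NULL) {
  if (is.null(m)) m <- stem_module(cfg$patch_size, cfg$base_dim,
                                   cfg$se_reduction)
  stem_fwd(m, image)$y
}
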